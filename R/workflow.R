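#' Covariate-stratified train/validation/test split
#'
#' The covariate (e.g. the BMI-like phantom covariate) is binned into
#' `n_strata` quantile bins; cases are shuffled within each bin (seeded) and
#' apportioned so that the global split sizes follow largest-remainder
#' rounding of `n * fractions` and every bin's allocation stays within one
#' case of proportional. Per-bin allocations use largest-remainder rounding
#' of cumulative bin totals, which makes the bin allocations sum exactly to
#' the global targets.
#'
#' @param covariate numeric covariate, one value per case.
#' @param fractions positive `(train, val, test)` fractions summing to 1.
#' @param n_strata number of quantile bins.
#' @param seed RNG seed for the within-bin shuffles.
#' @return list of class `split_spec_result` with integer index vectors
#'   `train`, `val`, `test` (disjoint, covering all cases).
#' @export
stratified_split <- function(covariate, fractions = c(0.8, 0.1, 0.1),
                             n_strata = 4L, seed = 1L) {
  n <- length(covariate)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be positive and sum to 1")
  if (anyNA(covariate)) stop("covariate must be present for all cases")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  qs <- stats::quantile(covariate, probs = seq(0, 1, length.out = n_strata + 1))
  bin <- cut(covariate, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  largest_remainder <- function(total, fr) {
    raw <- total * fr
    base <- floor(raw)
    rem <- raw - base
    extra <- total - sum(base)
    # deterministic tie-break: larger remainder first, then split order
    ord <- order(-rem, seq_along(fr))
    add <- integer(length(fr))
    if (extra > 0) add[ord[seq_len(extra)]] <- 1L
    base + add
  }
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  cum_n <- 0L
  cum_alloc <- c(0L, 0L, 0L)
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    idx <- idx[sample.int(length(idx))]
    cum_n <- cum_n + length(idx)
    want_cum <- largest_remainder(cum_n, fractions)
    take <- want_cum - cum_alloc
    if (any(take < 0)) { # guard against apportionment non-monotonicity
      take[take < 0] <- 0L
      take[which.max(take)] <- length(idx) - sum(take[-which.max(take)])
    }
    cum_alloc <- cum_alloc + take
    out$train <- c(out$train, idx[seq_len(take[1])])
    out$val <- c(out$val, idx[take[1] + seq_len(take[2])])
    out$test <- c(out$test, idx[take[1] + take[2] + seq_len(take[3])])
  }
  structure(out, class = "split_spec_result")
}

#' Configuration for an end-to-end phantom pipeline run
#'
#' One master seed derives per-stage seeds by fixed offsets (simulate +1,
#' split +2, train +3, quantify +4), so a full rerun with the same config is
#' numerically identical.
#'
#' @param region body region for the simulated cohort.
#' @param n_cases cohort size.
#' @param base_params [phantom_params()] shared by the cohort.
#' @param net a [net_config()] (tiny preset by default).
#' @param train a [train_config()].
#' @param augment an [augment_config()] or `NULL`.
#' @param fractions split fractions.
#' @param n_strata split strata.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(region = "thigh", n_cases = 25L,
                            base_params = phantom_params(
                              region, grid_shape = c(8L, 64L, 64L),
                              spacing = c(10, 1, 1)),
                            net = net_config_tiny(region),
                            train = train_config(epochs = 10L,
                                                 minibatches_per_epoch = 10L,
                                                 batch_size = 4L),
                            augment = NULL,
                            fractions = c(0.8, 0.1, 0.1),
                            n_strata = 4L,
                            seed = 1L) {
  structure(list(region = region, n_cases = as.integer(n_cases),
                 base_params = base_params, net = net, train = train,
                 augment = augment, fractions = fractions,
                 n_strata = as.integer(n_strata), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the simulate / split / train / segment / quantify / evaluate / agree
#' pipeline
#'
#' Executes the stages in order on a simulated cohort and writes all
#' artifacts into `out_dir`: `config.json`, `train_log.csv`, per-case
#' `metrics.csv` with a cohort summary, `profiles.json` (model-derived and
#' truth composition profiles of the test cases), `agreement.json`
#' (model-vs-truth volume agreement per compartment) and a structured
#' `log.txt` with per-stage wall time.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the in-memory results: `split`, `model`,
#'   `metrics`, `summary`, `profiles`, `agreement`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    if (verbose) message("stage: ", name)
    res <- force(expr)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    cat(sprintf("%s\t%.2fs\n", name, dt), file = logf, append = TRUE)
    res
  }
  cfg_json <- list(region = config$region, n_cases = config$n_cases,
                   seed = config$seed,
                   grid_shape = config$base_params$grid_shape,
                   imat_fraction = config$base_params$imat_fraction,
                   epochs = config$train$epochs,
                   fractions = config$fractions)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  cohort <- stage("simulate",
                  make_cohort(config$n_cases, config$base_params,
                              seed = config$seed + 1L))
  split <- stage("split",
                 stratified_split(cohort$covariates$bmi, config$fractions,
                                  config$n_strata, seed = config$seed + 2L))
  tc <- config$train
  tc$seed <- config$seed + 3L
  model <- stage("train",
                 train_model(cohort$cases[split$train], config$net, tc,
                             val_cases = cohort$cases[split$val],
                             augment = config$augment))
  utils::write.csv(model$log, file.path(out_dir, "train_log.csv"),
                   row.names = FALSE)
  schema <- label_schema(config$region)
  test_cases <- cohort$cases[split$test]
  preds <- stage("segment", lapply(test_cases, function(cs)
    predict_volume(model, znormalize(cs$volume), schema)))
  metrics <- stage("evaluate", lapply(seq_along(test_cases), function(i)
    evaluate_case(preds[[i]], test_cases[[i]]$truth)))
  summary <- aggregate_metrics(metrics)
  mdf <- do.call(rbind, lapply(seq_along(metrics), function(i)
    cbind(case = split$test[i], as.data.frame(metrics[[i]]))))
  utils::write.csv(mdf, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "metrics_summary.csv"),
                   row.names = FALSE)
  profiles <- stage("quantify", lapply(seq_along(test_cases), function(i) {
    list(case = split$test[i],
         model = composition_profile(test_cases[[i]]$volume, preds[[i]],
                                     seed = config$seed + 4L),
         truth = reference_profile(test_cases[[i]]))
  }))
  prof_json <- lapply(profiles, function(p)
    list(case = p$case,
         model = list(volumes_ml = as.list(p$model$volumes_ml),
                      circumference_mm = p$model$circumference_mm,
                      imat_percent = p$model$imat_percent),
         truth = list(volumes_ml = as.list(p$truth$volumes_ml),
                      circumference_mm = p$truth$circumference_mm,
                      imat_percent = p$truth$imat_percent)))
  jsonlite::write_json(prof_json, file.path(out_dir, "profiles.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  agreement <- stage("agree", {
    comps <- all_compartments(schema)
    res <- list()
    for (cp in comps) {
      a <- vapply(profiles, function(p) p$model$volumes_ml[[cp]], numeric(1))
      b <- vapply(profiles, function(p) p$truth$volumes_ml[[cp]], numeric(1))
      res[[cp]] <- if (length(a) >= 3)
        tryCatch({
          ag <- agreement_summary(a, b)
          list(pearson_r = ag$pearson_r, icc = ag$icc,
               bias = ag$bland_altman$bias,
               loa_low = ag$bland_altman$loa_low,
               loa_high = ag$bland_altman$loa_high, n = ag$n)
        }, error = function(e) list(error = conditionMessage(e)))
      else list(error = "too few test cases")
    }
    res
  })
  jsonlite::write_json(agreement, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(split = split, model = model, metrics = metrics,
                 summary = summary, profiles = profiles,
                 agreement = agreement))
}

#' Ablation comparison of input configurations
#'
#' Trains the fat-only, water-only and dual-sequence variants through the
#' identical loop on the same cohort and reports mean foreground validation
#' DSC per variant.
#'
#' @param cohort a [make_cohort()] result.
#' @param split a [stratified_split()] result.
#' @param region body region.
#' @param train a [train_config()].
#' @return data.frame with columns `input`, `mean_foreground_dsc`.
#' @export
run_ablation <- function(cohort, split, region = "thigh",
                         train = train_config(epochs = 5L,
                                              minibatches_per_epoch = 10L,
                                              batch_size = 4L)) {
  variants <- list(
    fat_only = net_config_tiny(region, in_channels = 1L, channels = "fat"),
    water_only = net_config_tiny(region, in_channels = 1L, channels = "water"),
    dual = net_config_tiny(region)
  )
  rows <- lapply(names(variants), function(v) {
    m <- train_model(cohort$cases[split$train], variants[[v]], train,
                     val_cases = cohort$cases[split$val])
    data.frame(input = v,
               mean_foreground_dsc = m$log$val_dsc[nrow(m$log)])
  })
  do.call(rbind, rows)
}
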