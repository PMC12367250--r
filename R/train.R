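#' Training configuration
#'
#' The production schedule is the default: 200 epochs of 250 minibatches of
#' 10 slices, SGD with Nesterov momentum 0.99, initial learning rate 0.01
#' decayed by the poly policy with power 0.9, He initialization, deep
#' supervision with per-resolution weights halving at each coarser level
#' (normalized to sum 1), and a soft-Dice + cross-entropy composite loss.
#' Desk-scale runs shrink `epochs`, `minibatches_per_epoch` and `batch_size`
#' through this config; the optimizer and loss are unchanged.
#'
#' @param epochs number of epochs (>= 1).
#' @param minibatches_per_epoch minibatches per epoch; slices are drawn
#'   uniformly with replacement so the count is independent of cohort size.
#' @param batch_size slices per minibatch.
#' @param lr0 initial learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param poly_power exponent of the poly learning-rate policy.
#' @param deep_supervision train with auxiliary losses at coarser decoder
#'   resolutions.
#' @param ds_weights per-resolution loss weights (finest first); normalized
#'   to sum 1. Default `(4, 2, 1)/7` for full, half and quarter resolution.
#' @param seed RNG seed for initialization, sampling and augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, minibatches_per_epoch = 250L,
                         batch_size = 10L, lr0 = 0.01, momentum = 0.99,
                         poly_power = 0.9, deep_supervision = TRUE,
                         ds_weights = c(4, 2, 1), seed = 1L) {
  stopifnot(epochs >= 1L, minibatches_per_epoch >= 1L, batch_size >= 1L,
            lr0 > 0, momentum >= 0, momentum < 1, poly_power > 0)
  ds_weights <- ds_weights / sum(ds_weights)
  structure(list(epochs = as.integer(epochs),
                 minibatches_per_epoch = as.integer(minibatches_per_epoch),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 momentum = momentum, poly_power = poly_power,
                 deep_supervision = deep_supervision,
                 ds_weights = ds_weights, seed = as.integer(seed)),
            class = "train_config")
}

#' Poly learning-rate schedule
#'
#' `lr = lr0 * (1 - epoch/epochs)^power`: starts at `lr0` for epoch 0 and
#' decays smoothly to 0 at the final epoch.
#'
#' @param epoch 0-based epoch index in `[0, epochs]`.
#' @param config a [train_config()].
#' @return Learning rate.
#' @export
poly_lr <- function(epoch, config) {
  if (epoch < 0 || epoch > config$epochs)
    stop("epoch must lie in [0, epochs]")
  config$lr0 * (1 - epoch / config$epochs)^config$poly_power
}

# per-pixel softmax over the channel axis of an H x W x K logit array,
# returned as an (H*W) x K matrix
softmax_mat <- function(logits) {
  d <- dim(logits)
  z <- matrix(logits, d[1] * d[2], d[3])
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Composite soft-Dice + cross-entropy segmentation loss
#'
#' Scores are unnormalized logits; a per-pixel softmax is applied internally.
#' The cross-entropy term is the mean negative log-probability of the target
#' class. The soft-Dice term is `1 - mean_c D_c` over foreground classes,
#' with `D_c = (2 * sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)` and
#' `eps = 1e-5`. The two terms are equally weighted. With `grad = TRUE` the
#' analytic gradient with respect to the logits is returned as well.
#'
#' @param scores `H x W x K` logit array.
#' @param target `H x W` integer matrix of class labels in `0..K-1`
#'   (0 = background).
#' @param grad also return `dscore`.
#' @param eps Dice smoothing constant.
#' @return list with `loss`, `ce`, `dice_loss` (and `dscore` when requested).
#' @export
composite_loss <- function(scores, target, grad = FALSE, eps = 1e-5) {
  d <- dim(scores)
  K <- d[3]
  if (!identical(dim(target), d[1:2]))
    stop("target shape must match score map")
  if (any(target < 0 | target >= K))
    stop("target labels must lie in 0..K-1 (class-count mismatch)")
  N <- d[1] * d[2]
  p <- softmax_mat(scores)
  tgt <- as.integer(target) + 1L
  idx <- cbind(seq_len(N), tgt)
  ce <- -mean(log(pmax(p[idx], 1e-300)))
  # one-hot columns implicitly via indexing
  fg <- 2:K
  A <- B <- numeric(K)
  tc_sum <- tabulate(tgt, nbins = K)
  for (c in fg) {
    tc <- tgt == c
    A[c] <- sum(p[tc, c])
    B[c] <- sum(p[, c]) + tc_sum[c]
  }
  Dc <- (2 * A[fg] + eps) / (B[fg] + eps)
  dice_loss <- 1 - mean(Dc)
  out <- list(loss = ce + dice_loss, ce = ce, dice_loss = dice_loss)
  if (!grad) return(out)
  # d(CE)/dz = (p - t)/N
  gz <- p / N
  gz[idx] <- gz[idx] - 1 / N
  # d(dice)/dp_c(v) = -(1/|fg|) * (2 t_v (B+eps) - (2A+eps)) / (B+eps)^2
  gp <- matrix(0, N, K)
  for (c in fg) {
    tc <- tgt == c
    denom <- (B[c] + eps)^2
    gp[, c] <- -(1 / length(fg)) * (2 * as.numeric(tc) * (B[c] + eps) -
                                      (2 * A[c] + eps)) / denom
  }
  # chain through softmax: gz_k = p_k (gp_k - sum_j gp_j p_j)
  dot <- rowSums(gp * p)
  gz <- gz + p * (gp - dot)
  out$dscore <- array(gz, d)
  out
}

# nearest-neighbor downsample of a label matrix by 2^(level-1)
downsample_target <- function(target, level) {
  f <- 2^(level - 1)
  if (f == 1) return(target)
  target[seq(1, nrow(target), by = f), seq(1, ncol(target), by = f),
         drop = FALSE]
}

#' Train the segmentation model
#'
#' SGD with Nesterov momentum on the composite soft-Dice + cross-entropy
#' loss, poly learning-rate decay, optional deep supervision (auxiliary
#' losses on nearest-neighbor-downsampled targets at coarser decoder
#' resolutions) and optional paired augmentation. Slices are drawn uniformly
#' with replacement. The run is fully determined by `config$seed`.
#'
#' @param cohort list of cases; each case is either a `phantom_case` or a
#'   list with elements `volume` ([dual_volume()]) and `truth`
#'   ([label_mask()]). Slices must already be at the network's input size.
#' @param net a [net_config()].
#' @param config a [train_config()].
#' @param val_cases optional held-out cases; mean foreground DSC is logged
#'   per epoch.
#' @param augment an [augment_config()] or `NULL` to disable augmentation.
#' @param znorm apply [znormalize()] to each case before slicing
#'   (default TRUE).
#' @param verbose print per-epoch progress.
#' @return A trained `bodycomp_unet`; `$log` holds epoch, lr, loss, val_dsc.
#' @export
train_model <- function(cohort, net, config = train_config(),
                        val_cases = NULL, augment = NULL, znorm = TRUE,
                        verbose = FALSE) {
  if (!length(cohort)) stop("cohort is empty")
  stopifnot(inherits(net, "net_config"), inherits(config, "train_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  slices <- extract_slices(cohort, net, znorm)
  val_prep <- if (!is.null(val_cases)) prepare_cases(val_cases, znorm)
  model <- build_unet(net)
  vel <- lapply(model$params, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b))))
  mu <- config$momentum
  use_ds <- config$deep_supervision && length(net$ds_levels) > 0
  ds_levels <- if (use_ds) net$ds_levels else integer(0)
  w_full <- if (use_ds) config$ds_weights[1] else 1
  log <- NULL
  for (epoch in seq_len(config$epochs)) {
    lr <- poly_lr(epoch - 1L, config)
    epoch_loss <- 0
    for (mb in seq_len(config$minibatches_per_epoch)) {
      pick <- sample.int(length(slices), config$batch_size, replace = TRUE)
      acc <- NULL
      mb_loss <- 0
      for (i in pick) {
        xs <- slices[[i]]$x; ys <- slices[[i]]$y
        if (!is.null(augment)) {
          au <- augment_pair(xs, ys, augment)
          xs <- au$image; ys <- au$mask
        }
        fwd <- unet_forward(model, xs, retain = TRUE, aux = use_ds)
        top <- composite_loss(fwd$logits, ys, grad = TRUE)
        loss_i <- w_full * top$loss
        gaux <- list()
        if (use_ds) {
          for (k in seq_along(ds_levels)) {
            lv <- ds_levels[k]
            wk <- config$ds_weights[k + 1]
            tk <- downsample_target(ys, lv)
            lk <- composite_loss(fwd$aux[[as.character(lv)]], tk, grad = TRUE)
            loss_i <- loss_i + wk * lk$loss
            gaux[[as.character(lv)]] <- wk * lk$dscore
          }
        }
        grads <- unet_backward(model, fwd, w_full * top$dscore, gaux)
        acc <- accumulate_grads(acc, grads, model$params)
        mb_loss <- mb_loss + loss_i
      }
      mb_loss <- mb_loss / length(pick)
      # Nesterov SGD: v <- mu v + g ; w <- w - lr (g + mu v)
      for (id in names(model$params)) {
        gW <- acc[[id]]$W / length(pick)
        gb <- acc[[id]]$b / length(pick)
        vel[[id]]$W <- mu * vel[[id]]$W + gW
        vel[[id]]$b <- mu * vel[[id]]$b + gb
        model$params[[id]]$W <- model$params[[id]]$W -
          lr * (gW + mu * vel[[id]]$W)
        model$params[[id]]$b <- model$params[[id]]$b -
          lr * (gb + mu * vel[[id]]$b)
      }
      epoch_loss <- epoch_loss + mb_loss
    }
    epoch_loss <- epoch_loss / config$minibatches_per_epoch
    val_dsc <- NA_real_
    if (!is.null(val_prep))
      val_dsc <- mean_foreground_dsc(model, val_prep)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr, loss = epoch_loss,
                                 val_dsc = val_dsc))
    if (verbose)
      message(sprintf("epoch %d/%d lr=%.5f loss=%.4f val_dsc=%s",
                      epoch, config$epochs, lr, epoch_loss,
                      ifelse(is.na(val_dsc), "-", sprintf("%.4f", val_dsc))))
  }
  model$log <- log
  model$train_config <- config
  model
}

# turn cases into a flat slice list of (x = H x W x Cin, y = H x W int)
extract_slices <- function(cohort, net, znorm) {
  prepped <- prepare_cases(cohort, znorm)
  slices <- list()
  for (case in prepped) {
    d <- dim(case$volume$fat)
    cfg_stub <- list(channels = net$channels)
    for (s in seq_len(d[3])) {
      slices[[length(slices) + 1L]] <-
        list(x = slice_channels(case$volume, s, cfg_stub),
             y = matrix(case$truth$labels[, , s], d[1], d[2]))
    }
  }
  slices
}

prepare_cases <- function(cases, znorm) {
  lapply(cases, function(cs) {
    vol <- if (znorm) znormalize(cs$volume) else cs$volume
    list(volume = vol, truth = cs$truth)
  })
}

# mean foreground DSC of a model over prepared validation cases
mean_foreground_dsc <- function(model, prepped) {
  vals <- vapply(prepped, function(cs) {
    pred <- predict_volume(model, cs$volume, cs$truth$schema)
    m <- evaluate_case(pred, cs$truth)
    raw <- m$compartment %in% names(cs$truth$schema$label_ids)
    mean(m$dsc[raw])
  }, numeric(1))
  mean(vals)
}

accumulate_grads <- function(acc, grads, params) {
  if (is.null(acc)) {
    acc <- lapply(params, function(p)
      list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b))))
  }
  for (id in names(grads)) {
    acc[[id]]$W <- acc[[id]]$W + grads[[id]]$W
    acc[[id]]$b <- acc[[id]]$b + grads[[id]]$b
  }
  acc
}
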