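#' Parameters for a synthetic dual-sequence phantom
#'
#' Phantoms emulate the geometry of abdominal and thigh axial MRI: nested
#' elliptical compartments with anisotropic voxels (thick slices, fine
#' in-plane spacing), a bright-fat / bright-water channel pair, and a planted
#' intermuscular-fat (IMAT) speckle fraction inside the muscle compartment.
#' Geometry is procedural (ellipses and annuli with seeded jitter), not an
#' anatomical atlas: it is designed to exercise every label, merge rule and
#' quantification step, not to look realistic.
#'
#' @param region `"abdomen"` or `"thigh"`.
#' @param grid_shape integer `(slices, rows, cols)`, all >= 8.
#' @param spacing `(dz, dy, dx)` mm; default 10 mm slices, 1 mm in-plane.
#' @param imat_fraction target fraction of muscle-compartment voxels replaced
#'   by bright fat speckle, in `[0, 1)`.
#' @param contrast per-tissue mean intensities for both channels; see
#'   [default_contrast()]. The fat-channel adipose intensity must exceed the
#'   fat-channel muscle intensity (K-means separability).
#' @param noise_sd SD of additive Gaussian noise per channel (intensity units).
#' @param seed integer seed; identical parameters give bit-identical phantoms.
#' @param body_scale,sat_scale multiplicative jitter applied to the overall
#'   body radius and to the subcutaneous-fat ring thickness (used by
#'   [make_cohort()] to link geometry to the BMI-like covariate).
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(region = c("abdomen", "thigh"),
                           grid_shape = c(8L, 96L, 96L),
                           spacing = c(10, 1, 1),
                           imat_fraction = 0.10,
                           contrast = default_contrast(region),
                           noise_sd = 40,
                           seed = 1L,
                           body_scale = 1,
                           sat_scale = 1) {
  region <- match.arg(region)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            imat_fraction >= 0, imat_fraction < 1, noise_sd >= 0,
            body_scale > 0, sat_scale > 0)
  adipose <- if (region == "abdomen") c("sSAT", "dSAT", "IPAT", "RPAT") else "SAT"
  muscle <- if (region == "abdomen") c("PM", "CM") else "muscle"
  if (min(contrast$fat[adipose]) <= max(contrast$fat[muscle]))
    stop("fat-channel adipose intensity must exceed muscle intensity")
  structure(list(region = region, grid_shape = grid_shape, spacing = spacing,
                 imat_fraction = imat_fraction, contrast = contrast,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 body_scale = body_scale, sat_scale = sat_scale),
            class = "phantom_params")
}

#' Default per-tissue channel intensities for phantoms
#'
#' Arbitrary units (MRI intensity is uncalibrated). Defaults put the
#' fat-channel adipose and muscle modes 650 units apart, i.e. more than 5
#' noise SDs at the default `noise_sd = 40`, so intensity-based IMAT
#' clustering is well posed.
#'
#' @param region `"abdomen"` or `"thigh"`.
#' @return list with named numeric vectors `fat` and `water` keyed by label
#'   name plus `"background"` and `"imat"`.
#' @export
default_contrast <- function(region = c("abdomen", "thigh")) {
  region <- match.arg(region)
  if (region == "abdomen") {
    list(
      fat = c(background = 20, VB = 300, PM = 150, CM = 150,
              sSAT = 800, dSAT = 800, IPAT = 800, RPAT = 800, imat = 800),
      water = c(background = 20, VB = 250, PM = 800, CM = 800,
                sSAT = 150, dSAT = 150, IPAT = 150, RPAT = 150, imat = 150)
    )
  } else {
    list(
      fat = c(background = 20, femur = 300, vessel = 120, SAT = 800,
              muscle = 150, imat = 800),
      water = c(background = 20, femur = 250, vessel = 600, SAT = 150,
                muscle = 800, imat = 150)
    )
  }
}

# rasterize one region's label geometry on a rows x cols grid.
# jit: named list of small multiplicative jitters (seeded upstream).
rasterize_labels <- function(region, rows, cols, body_scale, sat_scale, jit) {
  cy <- (rows + 1) / 2 * jit$cy
  cx <- (cols + 1) / 2 * jit$cx
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  lab <- matrix(0L, rows, cols)
  if (region == "thigh") {
    R0 <- 0.42 * min(rows, cols) * body_scale * jit$R
    rho <- sqrt((r - cy)^2 + (c - cx)^2)
    # SAT ring thickness scales with the BMI-like covariate
    r_mus <- R0 * max(0.35, min(0.92, 1 - 0.22 * sat_scale))
    lab[rho <= R0] <- 3L                       # SAT
    lab[rho <= r_mus] <- 4L                    # muscle
    r_fem <- max(2.2, 0.22 * R0)
    lab[sqrt((r - cy)^2 + (c - cx)^2) <= r_fem] <- 1L   # femur
    r_ves <- max(1.4, 0.06 * R0)
    for (ang in c(0.6, 2.5)) {                 # >= 2 vessel discs in muscle
      vy <- cy + 0.55 * r_mus * sin(ang + jit$va)
      vx <- cx + 0.55 * r_mus * cos(ang + jit$va)
      lab[sqrt((r - vy)^2 + (c - vx)^2) <= r_ves & lab == 4L] <- 2L
    }
  } else {
    b <- 0.40 * rows * body_scale * jit$R
    a <- 0.45 * cols * body_scale * jit$R
    rho <- sqrt(((r - cy) / b)^2 + ((c - cx) / a)^2)
    # ring cuts; SAT ring (sSAT+dSAT) thickens with sat_scale
    sat_out <- 1.0
    sat_in <- max(0.55, min(0.92, 1 - 0.28 * sat_scale))
    sat_mid <- (sat_out + sat_in) / 2
    cm_in <- sat_in - 0.10
    lab[rho <= sat_out] <- 4L                  # sSAT (outer ring)
    lab[rho <= sat_mid] <- 5L                  # dSAT (inner ring)
    lab[rho <= sat_in] <- 3L                   # core-muscle wall
    cav <- rho <= cm_in                        # visceral cavity
    lab[cav] <- 6L                             # IPAT by default
    # vertebral bone: posterior ellipse inside the cavity
    vb <- ((r - (cy + 0.42 * b)) / (0.16 * b))^2 +
          ((c - cx) / (0.14 * a))^2 <= 1 & cav
    # paired psoas muscles flanking the vertebra
    pm <- (((r - (cy + 0.30 * b)) / (0.12 * b))^2 +
           ((c - (cx - 0.20 * a)) / (0.10 * a))^2 <= 1 |
           ((r - (cy + 0.30 * b)) / (0.12 * b))^2 +
           ((c - (cx + 0.20 * a)) / (0.10 * a))^2 <= 1) & cav & !vb
    # retroperitoneal band: posterior cavity not occupied by VB/PM
    rp <- cav & r > cy + 0.16 * b & !vb & !pm
    lab[rp] <- 7L
    lab[pm] <- 2L
    lab[vb] <- 1L
  }
  lab
}

#' Generate one seeded synthetic dual-sequence phantom
#'
#' Builds the label geometry (identical across slices of a case), plants IMAT
#' speckle as seeded clusters of 1-3 voxels inside the muscle compartment
#' (core muscle for the abdomen, thigh muscle for the thigh) until exactly
#' `round(imat_fraction * n_muscle)` voxels are fat-bright, then renders both
#' channels from the contrast table and adds Gaussian noise. The same seed
#' always yields a bit-identical phantom; noise only affects intensities,
#' never the truth masks.
#'
#' @param params a [phantom_params()].
#' @return Object of class `phantom_case`: list with `volume` ([dual_volume()]),
#'   `truth` ([label_mask()]), `imat_truth` (logical array), `params`.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  gs <- params$grid_shape  # (slices, rows, cols)
  ns <- gs[1]; rows <- gs[2]; cols <- gs[3]
  schema <- label_schema(params$region)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  jit <- list(cy = 1 + stats::runif(1, -0.02, 0.02),
              cx = 1 + stats::runif(1, -0.02, 0.02),
              R = 1 + stats::runif(1, -0.03, 0.03),
              va = stats::runif(1, -0.3, 0.3))
  sl <- rasterize_labels(params$region, rows, cols,
                         params$body_scale, params$sat_scale, jit)
  labels <- array(rep(sl, ns), c(rows, cols, ns))
  counts <- table(factor(labels, levels = unname(schema$label_ids)))
  if (any(counts == 0L))
    stop("grid too small to place all compartments (missing: ",
         paste(names(schema$label_ids)[counts == 0L], collapse = ", "), ")")
  muscle_id <- if (params$region == "abdomen") schema$label_ids[["CM"]]
               else schema$label_ids[["muscle"]]
  imat <- plant_imat(labels, muscle_id, params$imat_fraction)
  # render channels
  lut_name <- c("background", names(schema$label_ids))[match(labels, c(0L, unname(schema$label_ids)))]
  fat <- array(params$contrast$fat[lut_name], dim(labels))
  water <- array(params$contrast$water[lut_name], dim(labels))
  fat[imat] <- params$contrast$fat[["imat"]]
  water[imat] <- params$contrast$water[["imat"]]
  if (params$noise_sd > 0) {
    fat <- fat + stats::rnorm(length(fat), 0, params$noise_sd)
    water <- water + stats::rnorm(length(water), 0, params$noise_sd)
  }
  structure(list(
    volume = dual_volume(fat, water, params$spacing),
    truth = label_mask(labels, schema, params$spacing),
    imat_truth = imat,
    params = params
  ), class = "phantom_case")
}

# plant clusters of 1-3 bright-fat voxels inside the muscle compartment until
# exactly round(f * n_muscle) voxels are marked (trimming the last cluster).
plant_imat <- function(labels, muscle_id, f) {
  d <- dim(labels)
  imat <- array(FALSE, d)
  mus <- which(labels == muscle_id)
  target <- round(f * length(mus))
  if (target == 0L) return(imat)
  avail <- rep(TRUE, length(mus))
  pos <- arrayInd(mus, d)
  key <- paste(pos[, 1], pos[, 2], pos[, 3])
  lookup <- seq_along(mus); names(lookup) <- key
  placed <- 0L
  while (placed < target && any(avail)) {
    v <- sample(which(avail), 1L)
    want <- sample(1:3, 1L)
    cluster <- v
    while (length(cluster) < want) {
      # in-plane 4-neighbours of the cluster that are available muscle voxels
      p <- pos[cluster, , drop = FALSE]
      nb <- rbind(cbind(p[, 1] + 1L, p[, 2], p[, 3]),
                  cbind(p[, 1] - 1L, p[, 2], p[, 3]),
                  cbind(p[, 1], p[, 2] + 1L, p[, 3]),
                  cbind(p[, 1], p[, 2] - 1L, p[, 3]))
      k <- paste(nb[, 1], nb[, 2], nb[, 3])
      cand <- unname(lookup[k[k %in% names(lookup)]])
      cand <- setdiff(cand[avail[cand]], cluster)
      if (!length(cand)) break
      cluster <- c(cluster, if (length(cand) == 1L) cand else sample(cand, 1L))
    }
    cluster <- cluster[seq_len(min(length(cluster), target - placed))]
    avail[cluster] <- FALSE
    imat[mus[cluster]] <- TRUE
    placed <- placed + length(cluster)
  }
  imat
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("phantom_case (", x$params$region, "), grid ",
      paste(x$params$grid_shape, collapse = "x"),
      ", planted IMAT fraction ", signif(x$params$imat_fraction, 3),
      " (", sum(x$imat_truth), " voxels)\n", sep = "")
  invisible(x)
}

#' Simulate a seeded phantom cohort with a BMI-like covariate
#'
#' Draws `n` phantoms whose geometry and planted IMAT vary around the base
#' parameters: the BMI-like covariate is lognormal (median 25, sdlog 0.15)
#' and drives the subcutaneous-fat ring thickness, the overall body radius
#' gets ~3% jitter, and per-case IMAT fractions are Beta-distributed with
#' mean equal to the configured `imat_fraction` (concentration 50). The
#' covariate table feeds BMI-referenced stratified splitting.
#'
#' @param n number of cases (>= 1).
#' @param base a [phantom_params()] giving the shared defaults.
#' @param seed master seed for the cohort.
#' @return list with `cases` (list of `phantom_case`) and `covariates`
#'   (data.frame: case_id, bmi, imat_fraction, seed).
#' @export
make_cohort <- function(n, base = phantom_params(), seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  case_seed <- sample.int(.Machine$integer.max - 1L, n)
  bmi <- stats::rlnorm(n, log(25), 0.15)
  body <- stats::rnorm(n, 1, 0.03)
  f0 <- base$imat_fraction
  fr <- if (f0 > 0) stats::rbeta(n, f0 * 50, (1 - f0) * 50) else rep(0, n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base
    p$seed <- case_seed[i]
    p$imat_fraction <- fr[i]
    p$body_scale <- max(0.85, min(1.15, body[i]))
    p$sat_scale <- max(0.5, min(2.0, bmi[i] / 25))
    cases[[i]] <- generate_phantom(p)
  }
  list(cases = cases,
       covariates = data.frame(case_id = seq_len(n), bmi = bmi,
                               imat_fraction = fr, seed = case_seed))
}

#' Exact ground-truth composition profile of a phantom
#'
#' Volumes come from exhaustive voxel counts times voxel volume; the IMAT
#' fraction comes from the planted `imat_truth` mask; the bone circumference
#' is measured on the truth mask with the package's contour convention
#' (see [circumference_of()]).
#'
#' @param case a `phantom_case`.
#' @return A [composition_profile] computed from the ground truth.
#' @export
reference_profile <- function(case) {
  stopifnot(inherits(case, "phantom_case"))
  profile_from_parts(
    mask = case$truth,
    imat_mask = case$imat_truth,
    source = "truth"
  )
}

# save/restore global RNG state so seeded generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
}
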