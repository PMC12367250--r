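#' Training-time augmentation configuration
#'
#' Each transform fires independently with probability `apply_probability`
#' (default 0.5). Parameter ranges follow the common conventions for U-Net
#' segmentation training: rotation within +/-30 degrees, isotropic scaling in
#' `[0.7, 1.4]`, additive Gaussian noise with variance drawn from
#' `[0, 0.1]` (on Z-scored intensities), Gaussian blur with sigma in
#' `[0.5, 1.0]`, gamma correction in `[0.7, 1.5]`, and mirroring along either
#' in-plane axis. The 0.5 firing probability is the one fixed design
#' constant; every range is overridable, and a transform is disabled by
#' setting its range to `NULL`.
#'
#' @param apply_probability per-transform firing probability in `[0, 1]`.
#' @param rotation_deg range of rotation angles (degrees).
#' @param scale range of isotropic scale factors.
#' @param noise_variance range of additive-noise variances.
#' @param blur_sigma range of blur SDs (pixels).
#' @param gamma range of gamma exponents.
#' @param mirror_axes axes eligible for mirroring (1 = rows, 2 = cols).
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(apply_probability = 0.5,
                           rotation_deg = c(-30, 30),
                           scale = c(0.7, 1.4),
                           noise_variance = c(0, 0.1),
                           blur_sigma = c(0.5, 1.0),
                           gamma = c(0.7, 1.5),
                           mirror_axes = c(1L, 2L)) {
  stopifnot(apply_probability >= 0, apply_probability <= 1)
  chk <- function(r) is.null(r) || (length(r) == 2L && r[1] <= r[2])
  stopifnot(chk(rotation_deg), chk(scale), chk(noise_variance),
            chk(blur_sigma), chk(gamma))
  structure(list(apply_probability = apply_probability,
                 rotation_deg = rotation_deg, scale = scale,
                 noise_variance = noise_variance, blur_sigma = blur_sigma,
                 gamma = gamma, mirror_axes = mirror_axes),
            class = "augment_config")
}

# draw which transforms fire and their parameters from the current RNG stream
draw_augment_plan <- function(config) {
  p <- config$apply_probability
  fire <- function(range) !is.null(range) && stats::runif(1) < p
  plan <- list()
  plan$rotate <- if (fire(config$rotation_deg))
    stats::runif(1, config$rotation_deg[1], config$rotation_deg[2])
  plan$scale <- if (fire(config$scale))
    stats::runif(1, config$scale[1], config$scale[2])
  plan$mirror <- if (length(config$mirror_axes) && stats::runif(1) < p)
    config$mirror_axes[sample.int(length(config$mirror_axes), 1L)]
  plan$noise_var <- if (fire(config$noise_variance))
    stats::runif(1, config$noise_variance[1], config$noise_variance[2])
  plan$blur <- if (fire(config$blur_sigma))
    stats::runif(1, config$blur_sigma[1], config$blur_sigma[2])
  plan$gamma <- if (fire(config$gamma))
    stats::runif(1, config$gamma[1], config$gamma[2])
  plan
}

# inverse-mapped affine resampling about the slice center.
# interp = "bilinear" (image) or "nearest" (mask); outside pixels -> fill.
affine_slice <- function(m, angle_deg = 0, scale = 1,
                         interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gi <- matrix(seq_len(H), H, W) - cy
  gj <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse transform: rotate by -theta, scale by 1/s
  si <- (cos(th) * gi + sin(th) * gj) / scale + cy
  sj <- (-sin(th) * gi + cos(th) * gj) / scale + cx
  if (interp == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    out <- matrix(fill, H, W)
    out[ok] <- m[cbind(ri[ok], rj[ok])]
    storage.mode(out) <- storage.mode(m)
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    cl <- function(i, j) {
      ok <- i >= 1 & i <= H & j >= 1 & j <= W
      v <- matrix(fill, H, W)
      v[ok] <- m[cbind(i[ok], j[ok])]
      v
    }
    out <- (1 - fi) * (1 - fj) * cl(i0, j0) + fi * (1 - fj) * cl(i0 + 1, j0) +
           (1 - fi) * fj * cl(i0, j0 + 1) + fi * fj * cl(i0 + 1, j0 + 1)
  }
  out
}

#' Jointly augment one image slice and its mask
#'
#' Geometric transforms (rotation, scaling, mirroring) are applied
#' identically to image and mask — bilinear interpolation for the image,
#' nearest neighbor for the mask, so the mask value set never grows.
#' Intensity transforms (additive Gaussian noise, Gaussian blur, gamma
#' correction) touch the image only. Draws come from the current RNG stream:
#' seed with `set.seed()` for reproducibility.
#'
#' @param image_slice `H x W x C` numeric array (or `H x W` matrix).
#' @param mask_slice `H x W` integer matrix.
#' @param config an [augment_config()].
#' @return list with `image`, `mask`, and the sampled `plan`.
#' @export
augment_pair <- function(image_slice, mask_slice, config = augment_config()) {
  if (is.matrix(image_slice)) dim(image_slice) <- c(dim(image_slice), 1L)
  if (!identical(dim(image_slice)[1:2], dim(mask_slice)))
    stop("image and mask slices must share in-plane shape")
  plan <- draw_augment_plan(config)
  img <- image_slice; msk <- mask_slice
  if (!is.null(plan$rotate) || !is.null(plan$scale)) {
    ang <- if (is.null(plan$rotate)) 0 else plan$rotate
    sc <- if (is.null(plan$scale)) 1 else plan$scale
    for (ch in seq_len(dim(img)[3]))
      img[, , ch] <- affine_slice(img[, , ch], ang, sc, "bilinear")
    msk <- affine_slice(msk, ang, sc, "nearest", fill = 0L)
  }
  if (!is.null(plan$mirror)) {
    rev_idx <- function(n) n:1
    if (plan$mirror == 1L) {
      img <- img[rev_idx(dim(img)[1]), , , drop = FALSE]
      msk <- msk[rev_idx(nrow(msk)), , drop = FALSE]
    } else {
      img <- img[, rev_idx(dim(img)[2]), , drop = FALSE]
      msk <- msk[, rev_idx(ncol(msk)), drop = FALSE]
    }
  }
  if (!is.null(plan$noise_var) && plan$noise_var > 0)
    img <- img + array(stats::rnorm(length(img), 0, sqrt(plan$noise_var)),
                       dim(img))
  if (!is.null(plan$blur))
    for (ch in seq_len(dim(img)[3]))
      img[, , ch] <- gauss_smooth2d(img[, , ch], plan$blur)
  if (!is.null(plan$gamma)) {
    rng <- range(img)
    if (diff(rng) > 1e-12)
      img <- ((img - rng[1]) / diff(rng))^plan$gamma * diff(rng) + rng[1]
  }
  list(image = img, mask = msk, plan = plan)
}
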