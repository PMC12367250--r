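#' Dual-sequence volume container
#'
#' Holds co-registered fat-sequence and water-sequence voxel grids. Arrays are
#' stored `[row, col, slice]` (column-major, slices contiguous); spacing is
#' reported `(dz, dy, dx)` in mm, i.e. slice thickness first, then in-plane
#' row/column spacing. The fat image is bright in adipose tissue, the water
#' image bright in lean tissue; the pair forms the two input channels of the
#' segmentation model.
#'
#' @param fat,water 3D numeric arrays of identical dimension `[row, col, slice]`.
#' @param spacing numeric length-3 `(dz, dy, dx)` mm, all > 0.
#' @return Object of class `dual_volume`.
#' @export
dual_volume <- function(fat, water, spacing) {
  fat <- as_vol3d(fat)
  water <- as_vol3d(water)
  if (!identical(dim(fat), dim(water)))
    stop("fat and water arrays must share dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (dz, dy, dx) in mm")
  structure(list(fat = fat, water = water, spacing = spacing),
            class = "dual_volume")
}

as_vol3d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 3D array [row, col, slice]")
  storage.mode(x) <- "double"
  x
}

#' @export
print.dual_volume <- function(x, ...) {
  d <- dim(x$fat)
  cat(sprintf("dual_volume: %d x %d x %d voxels, spacing (dz,dy,dx) = (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Integer compartment mask sharing a volume's geometry
#'
#' @param labels 3D integer array `[row, col, slice]`; 0 is background and every
#'   nonzero value must be a label id of `schema`.
#' @param schema a [label_schema()].
#' @param spacing `(dz, dy, dx)` mm.
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(labels, schema, spacing) {
  labels <- as_vol3d(labels)
  storage.mode(labels) <- "integer"
  stopifnot(inherits(schema, "label_schema"))
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, c(0L, unname(schema$label_ids)))
  if (length(bad))
    stop("mask contains values outside the ", schema$region, " schema: ",
         paste(bad, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive numbers (dz, dy, dx) in mm")
  structure(list(labels = labels, schema = schema, spacing = spacing),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_mask (%s): %d x %d x %d voxels\n",
              x$schema$region, d[1], d[2], d[3]))
  tab <- table(factor(as.vector(x$labels),
                      levels = c(0L, unname(x$schema$label_ids)),
                      labels = c("background", names(x$schema$label_ids))))
  print(tab)
  invisible(x)
}

same_geometry <- function(a, b) {
  da <- dim(if (inherits(a, "dual_volume")) a$fat else a$labels)
  db <- dim(if (inherits(b, "dual_volume")) b$fat else b$labels)
  sa <- a$spacing; sb <- b$spacing
  identical(da, db) && isTRUE(all.equal(sa, sb, tolerance = 1e-8))
}

#' Per-channel Z-score normalization
#'
#' Each channel is independently standardized to mean 0 and unit SD over all
#' voxels of the 3D volume (population SD, denominator N). A constant channel
#' maps to all zeros rather than dividing by zero.
#'
#' @param volume a [dual_volume()].
#' @return A `dual_volume` with standardized channels and unchanged spacing.
#' @export
znormalize <- function(volume) {
  stopifnot(inherits(volume, "dual_volume"))
  if (length(volume$fat) < 2L) stop("volume must contain at least 2 voxels")
  zn <- function(x) {
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s < 1e-12) return(array(0, dim(x)))
    (x - m) / s
  }
  dual_volume(zn(volume$fat), zn(volume$water), volume$spacing)
}

# separable 1D natural-cubic-spline resampling of a matrix to new dims.
# Output pixel centers map to input coordinates (center-aligned):
#   p_in = (j + 0.5) * old_dim/new_dim - 0.5   in 0-based pixel units,
# which reduces to the identity when dims are unchanged.
resample_matrix_spline <- function(m, new_dim) {
  r0 <- nrow(m); c0 <- ncol(m)
  r1 <- new_dim[1]; c1 <- new_dim[2]
  if (r1 == r0 && c1 == c0) return(m)
  map <- function(n_new, n_old) {
    p <- (seq_len(n_new) - 0.5) * n_old / n_new - 0.5
    pmin(pmax(p, 0), n_old - 1)
  }
  if (r1 != r0) {
    xo <- map(r1, r0)
    m <- apply(m, 2, function(col)
      stats::spline(x = 0:(r0 - 1), y = col, xout = xo, method = "natural")$y)
    dim(m) <- c(r1, c0)
  }
  if (c1 != c0) {
    xo <- map(c1, c0)
    m <- t(apply(m, 1, function(row)
      stats::spline(x = 0:(c0 - 1), y = row, xout = xo, method = "natural")$y))
    dim(m) <- c(r1, c1)
  }
  m
}

resample_matrix_nn <- function(m, new_dim) {
  r0 <- nrow(m); c0 <- ncol(m)
  if (new_dim[1] == r0 && new_dim[2] == c0) return(m)
  map_idx <- function(n_new, n_old) {
    p <- (seq_len(n_new) - 0.5) * n_old / n_new - 0.5
    pmin(pmax(round(p) + 1, 1), n_old)
  }
  m[map_idx(new_dim[1], r0), map_idx(new_dim[2], c0), drop = FALSE]
}

#' In-plane resampling of a volume/mask pair to a target spacing
#'
#' Resamples each axial slice to the target in-plane spacing: third-order
#' (natural cubic) spline interpolation for the image channels and
#' nearest-neighbor interpolation for the mask, so no new label values can
#' appear. The slice axis is left untouched (processing is slice-wise to
#' respect the anisotropy of the data). The output in-plane dimension is
#' `round_half_up(old_dim * old_spacing / target_spacing)`.
#'
#' @param volume a [dual_volume()].
#' @param mask a [label_mask()] sharing the volume's geometry, or `NULL`.
#' @param target_inplane numeric `(dy, dx)` mm, default `c(0.820, 0.820)`.
#' @return list with elements `volume` and `mask` (NULL if no mask given).
#' @export
resample_pair <- function(volume, mask = NULL, target_inplane = c(0.820, 0.820)) {
  stopifnot(inherits(volume, "dual_volume"), length(target_inplane) == 2L,
            all(target_inplane > 0))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "label_mask"))
    if (!same_geometry(volume, mask))
      stop("volume and mask must share geometry")
  }
  d <- dim(volume$fat)
  old_sp <- volume$spacing[2:3]
  new_dim <- c(floor(d[1] * old_sp[1] / target_inplane[1] + 0.5),
               floor(d[2] * old_sp[2] / target_inplane[2] + 0.5))
  new_spacing <- c(volume$spacing[1], target_inplane)
  rf <- array(0, c(new_dim, d[3]))
  rw <- array(0, c(new_dim, d[3]))
  rm <- if (!is.null(mask)) array(0L, c(new_dim, d[3]))
  for (s in seq_len(d[3])) {
    rf[, , s] <- resample_matrix_spline(volume$fat[, , s], new_dim)
    rw[, , s] <- resample_matrix_spline(volume$water[, , s], new_dim)
    if (!is.null(mask))
      rm[, , s] <- resample_matrix_nn(mask$labels[, , s], new_dim)
  }
  out_vol <- dual_volume(rf, rw, new_spacing)
  out_mask <- if (!is.null(mask)) label_mask(rm, mask$schema, new_spacing)
  list(volume = out_vol, mask = out_mask)
}

# centered crop/pad of one matrix; pad with `fill`.
crop_pad_matrix <- function(m, size, fill = 0) {
  d <- dim(m)
  out <- matrix(fill, size[1], size[2])
  # source and destination index ranges per axis
  rng <- function(old, new) {
    if (old >= new) {
      start <- floor((old - new) / 2)    # crop offset into source
      list(src = (start + 1):(start + new), dst = 1:new, off = -start)
    } else {
      start <- floor((new - old) / 2)    # pad offset into destination
      list(src = 1:old, dst = (start + 1):(start + old), off = start)
    }
  }
  ri <- rng(d[1], size[1]); ci <- rng(d[2], size[2])
  out[ri$dst, ci$dst] <- m[ri$src, ci$src]
  storage.mode(out) <- storage.mode(m)
  attr(out, "offsets") <- c(ri$off, ci$off)
  out
}

#' Centered in-plane crop or zero-pad to a fixed size
#'
#' Crops centrally when the slice is larger than `size` and pads symmetrically
#' (zeros for the image, background for the mask) when smaller. The returned
#' objects carry a `crop_pad_info` attribute (original in-plane dims and
#' per-axis offsets) so predictions can be mapped back to the original
#' geometry with [restore_geometry()].
#'
#' @param volume a [dual_volume()].
#' @param mask a [label_mask()] or `NULL`.
#' @param size `(rows, cols)`, default `c(512, 512)`.
#' @return list with `volume` and `mask`.
#' @export
crop_pad <- function(volume, mask = NULL, size = c(512, 512)) {
  stopifnot(inherits(volume, "dual_volume"), length(size) == 2L, all(size > 0))
  if (!is.null(mask) && !same_geometry(volume, mask))
    stop("volume and mask must share geometry")
  d <- dim(volume$fat)
  cf <- array(0, c(size, d[3])); cw <- array(0, c(size, d[3]))
  cm <- if (!is.null(mask)) array(0L, c(size, d[3]))
  off <- NULL
  for (s in seq_len(d[3])) {
    a <- crop_pad_matrix(volume$fat[, , s], size)
    off <- attr(a, "offsets")
    cf[, , s] <- a
    cw[, , s] <- crop_pad_matrix(volume$water[, , s], size)
    if (!is.null(mask))
      cm[, , s] <- crop_pad_matrix(mask$labels[, , s], size, fill = 0L)
  }
  info <- list(orig_dim = d[1:2], size = size, offsets = off)
  out_vol <- dual_volume(cf, cw, volume$spacing)
  attr(out_vol, "crop_pad_info") <- info
  out_mask <- NULL
  if (!is.null(mask)) {
    out_mask <- label_mask(cm, mask$schema, mask$spacing)
    attr(out_mask, "crop_pad_info") <- info
  }
  list(volume = out_vol, mask = out_mask)
}

#' Map a cropped/padded mask back to its original in-plane geometry
#'
#' Inverse of the [crop_pad()] transform: padded margins are discarded and
#' cropped margins restored as background.
#'
#' @param mask a [label_mask()] produced at the crop/pad geometry.
#' @param info the `crop_pad_info` attribute recorded by [crop_pad()]
#'   (taken from `mask` itself when omitted).
#' @return A `label_mask` with the original in-plane dimensions.
#' @export
restore_geometry <- function(mask, info = attr(mask, "crop_pad_info")) {
  stopifnot(inherits(mask, "label_mask"), !is.null(info))
  d <- dim(mask$labels)
  out <- array(0L, c(info$orig_dim, d[3]))
  for (ax in 1:2) stopifnot(d[ax] == info$size[ax])
  undo <- function(old, new, off) {
    # off recorded source-relative: negative = crop offset, positive = pad
    if (old >= new) list(dst = (-off + 1):(-off + new), src = 1:new)
    else list(dst = 1:old, src = (off + 1):(off + old))
  }
  ri <- undo(info$orig_dim[1], info$size[1], info$offsets[1])
  ci <- undo(info$orig_dim[2], info$size[2], info$offsets[2])
  for (s in seq_len(d[3]))
    out[ri$dst, ci$dst, s] <- mask$labels[ri$src, ci$src, s]
  label_mask(out, mask$schema, mask$spacing)
}

#' Write / read a dual volume as NIfTI
#'
#' The fat and water channels are written as `<prefix>_fat.nii.gz` and
#' `<prefix>_water.nii.gz` with voxel spacing in the header (array dimension
#' order `[row, col, slice]` maps to header pixdim `(dy, dx, dz)`). A JSON
#' sidecar `<prefix>.json` records any parameter list passed.
#'
#' @param volume a [dual_volume()].
#' @param prefix output path prefix.
#' @param sidecar optional list serialized to `<prefix>.json`.
#' @return `write_dual_volume` invisibly returns the file paths;
#'   `read_dual_volume` returns a `dual_volume`.
#' @export
write_dual_volume <- function(volume, prefix, sidecar = NULL) {
  stopifnot(inherits(volume, "dual_volume"))
  pd <- volume$spacing[c(2, 3, 1)]
  paths <- c(fat = paste0(prefix, "_fat.nii.gz"),
             water = paste0(prefix, "_water.nii.gz"))
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pd
    img
  }
  RNifti::writeNifti(as_img(volume$fat), paths["fat"])
  RNifti::writeNifti(as_img(volume$water), paths["water"])
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_dual_volume
#' @export
read_dual_volume <- function(prefix) {
  f <- RNifti::readNifti(paste0(prefix, "_fat.nii.gz"))
  w <- RNifti::readNifti(paste0(prefix, "_water.nii.gz"))
  pd <- RNifti::pixdim(f)
  dual_volume(array(as.vector(f), dim(f)), array(as.vector(w), dim(w)),
              spacing = pd[c(3, 1, 2)])
}

#' Write / read a label mask as integer NIfTI
#'
#' @param mask a [label_mask()].
#' @param path output `.nii.gz` path.
#' @param region region of the schema used on read.
#' @return `read_label_mask` returns a `label_mask`.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  pd <- mask$spacing[c(2, 3, 1)]
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path, region = c("abdomen", "thigh")) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  label_mask(array(as.integer(img), dim(img)), label_schema(region),
             spacing = pd[c(3, 1, 2)])
}
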