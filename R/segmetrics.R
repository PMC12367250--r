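#' Voxel-wise confusion counts for one compartment
#'
#' The compartment is treated as the union of its label ids in both masks
#' (derived compartments such as SAT or VAT are evaluated on merged labels),
#' then counted voxel-wise over the whole 3D case.
#'
#' @param pred,truth [label_mask()] objects sharing geometry and schema.
#' @param compartment compartment name or integer id set.
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth, compartment) {
  stopifnot(inherits(pred, "label_mask"), inherits(truth, "label_mask"))
  if (!same_geometry(pred, truth)) stop("pred and truth must share geometry")
  if (!identical(pred$schema$region, truth$schema$region))
    stop("pred and truth must share the label schema")
  ids <- compartment_ids(truth$schema, compartment)
  p <- pred$labels %in% ids
  t <- truth$labels %in% ids
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Segmentation overlap metrics from confusion counts
#'
#' The five per-compartment metrics:
#' \itemize{
#'   \item `dsc` — Dice similarity coefficient `2 TP / (2 TP + FP + FN)`;
#'   \item `jaccard` — `TP / (TP + FP + FN)`;
#'   \item `tpf` — true-positive fraction (sensitivity) `TP / (TP + FN)`;
#'   \item `osr` — oversegmentation rate `FP / (TP + FN)`;
#'   \item `area_difference_pct` — relative segmented-area difference
#'     `((TP+FP) - (TP+FN)) / (TP+FN) * 100`, reported as an absolute value by
#'     default (`signed = TRUE` exposes the signed variant).
#' }
#' A compartment empty in both masks gives `dsc = jaccard = 1` by convention
#' (a perfect prediction on a compartment-free case should not drag
#' averages); `tpf`, `osr` and the area difference are undefined (`NA`) when
#' the truth compartment is empty.
#'
#' @param c a [confusion_counts()] object.
#' @param signed for `area_difference_pct`: keep the sign (default `FALSE`).
#' @return A single numeric value.
#' @name overlap_metrics
NULL

#' @rdname overlap_metrics
#' @export
dsc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) return(1.0)
  2 * c$tp / denom
}

#' @rdname overlap_metrics
#' @export
jaccard <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  denom <- c$tp + c$fp + c$fn
  if (denom == 0) return(1.0)
  c$tp / denom
}

#' @rdname overlap_metrics
#' @export
tpf <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0) return(NA_real_)
  c$tp / (c$tp + c$fn)
}

#' @rdname overlap_metrics
#' @export
osr <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0) return(NA_real_)
  c$fp / (c$tp + c$fn)
}

#' @rdname overlap_metrics
#' @export
area_difference_pct <- function(c, signed = FALSE) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0) return(NA_real_)
  v <- ((c$tp + c$fp) - (c$tp + c$fn)) / (c$tp + c$fn) * 100
  if (signed) v else abs(v)
}

#' All five metrics for every raw and derived compartment of one case
#'
#' Metrics are computed over the full 3D voxel sets of the case; `slice`
#' restricts the evaluation to one axial slice (a debugging aid).
#'
#' @param pred,truth [label_mask()] objects sharing geometry and schema.
#' @param slice optional single slice index.
#' @return data.frame of class `case_metrics`: one row per compartment with
#'   columns `compartment`, `dsc`, `jaccard`, `tpf`, `osr`, `area_diff_pct`.
#' @export
evaluate_case <- function(pred, truth, slice = NULL) {
  if (!is.null(slice)) {
    take <- function(m) label_mask(m$labels[, , slice, drop = FALSE],
                                   m$schema, m$spacing)
    pred <- take(pred); truth <- take(truth)
  }
  comps <- all_compartments(truth$schema)
  rows <- lapply(comps, function(cp) {
    cc <- confusion_counts(pred, truth, cp)
    data.frame(compartment = cp, dsc = dsc(cc), jaccard = jaccard(cc),
               tpf = tpf(cc), osr = osr(cc),
               area_diff_pct = area_difference_pct(cc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("case_metrics", class(out))
  out
}

#' Cohort mean and SD of per-case metrics
#'
#' Cases are weighted equally; `NA` entries (compartments absent from a
#' case's ground truth) are dropped per metric.
#'
#' @param metrics_list list of [evaluate_case()] results.
#' @return data.frame with one row per compartment and `<metric>_mean` /
#'   `<metric>_sd` columns.
#' @export
aggregate_metrics <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1L)
  all <- do.call(rbind, lapply(metrics_list, as.data.frame))
  cols <- c("dsc", "jaccard", "tpf", "osr", "area_diff_pct")
  out <- NULL
  for (cp in unique(all$compartment)) {
    sub <- all[all$compartment == cp, ]
    row <- data.frame(compartment = cp, n = nrow(sub))
    for (m in cols) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(sub[[m]], na.rm = TRUE)
    }
    out <- rbind(out, row)
  }
  out
}
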