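# shared fixtures: all built in code at test time

thigh_params <- function(grid = c(8L, 64L, 64L), imat = 0.1, seed = 7L,
                         noise_sd = 40, ...) {
  phantom_params("thigh", grid_shape = grid, spacing = c(10, 1, 1),
                 imat_fraction = imat, noise_sd = noise_sd, seed = seed, ...)
}

abdomen_params <- function(grid = c(8L, 96L, 96L), imat = 0.1, seed = 7L,
                           noise_sd = 40, ...) {
  phantom_params("abdomen", grid_shape = grid, spacing = c(10, 1, 1),
                 imat_fraction = imat, noise_sd = noise_sd, seed = seed, ...)
}

# random label masks on a small grid (both sharing a schema), for metric tests
random_mask_pair <- function(dim3 = c(8L, 8L, 8L), region = "thigh") {
  sch <- label_schema(region)
  ids <- c(0L, unname(sch$label_ids))
  a <- array(sample(ids, prod(dim3), replace = TRUE), dim3)
  b <- array(sample(ids, prod(dim3), replace = TRUE), dim3)
  list(pred = label_mask(a, sch, c(1, 1, 1)),
       truth = label_mask(b, sch, c(1, 1, 1)))
}

# brute-force voxel-counting metric oracle: explicit double loop over the
# flattened arrays, no vectorized set operations shared with the implementation
brute_force_metrics <- function(pred, truth, ids) {
  p <- as.vector(pred$labels); t <- as.vector(truth$labels)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(p)) {
    pi <- p[i] %in% ids; ti <- t[i] %in% ids
    if (pi && ti) tp <- tp + 1L
    else if (pi && !ti) fp <- fp + 1L
    else if (!pi && ti) fn <- fn + 1L
    else tn <- tn + 1L
  }
  dsc <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  jac <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  tpf <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  osr <- if (tp + fn == 0) NA_real_ else fp / (tp + fn)
  ad <- if (tp + fn == 0) NA_real_ else abs((tp + fp) - (tp + fn)) / (tp + fn) * 100
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       dsc = dsc, jaccard = jac, tpf = tpf, osr = osr, area_diff_pct = ad)
}

# slow reference soft-Dice and cross-entropy, coded independently of
# composite_loss (explicit one-hot arrays and per-class loops)
oracle_dice_ce <- function(scores, target, eps = 1e-5) {
  d <- dim(scores); K <- d[3]; N <- d[1] * d[2]
  p <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    z <- scores[i, j, ]
    e <- exp(z - max(z))
    p[i, j, ] <- e / sum(e)
  }
  ce <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ce <- ce - log(p[i, j, target[i, j] + 1])
  }
  ce <- ce / N
  dices <- numeric(K - 1)
  for (c in 2:K) {
    tmask <- (target == c - 1) * 1
    A <- sum(p[, , c] * tmask)
    B <- sum(p[, , c]) + sum(tmask)
    dices[c - 1] <- (2 * A + eps) / (B + eps)
  }
  list(ce = ce, dice_loss = 1 - mean(dices))
}
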