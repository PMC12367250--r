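#' Network configuration for the dual-channel 2D U-Net
#'
#' The full preset is the production architecture: 6 encoder blocks
#' with filter pairs (32,32), (64,64), (128,128), (256,256), (480,480),
#' (480,480), a (480,480) bottleneck, mirrored decoder, 2x2 max pooling and
#' 2x2 transposed convolutions, two 3x3 convolutions (pad 1) per block each
#' followed by LeakyReLU (negative slope 0.01), and a 1x1 output head. A
#' 512x512 input reaches an 8x8 bottleneck. Output channels are
#' `n_labels + 1` (softmax over background plus foreground labels): 8 for the
#' abdomen, 5 for the thigh. The `tiny` preset (4 levels, filters capped at
#' 64) is for desk-scale experiments.
#'
#' @param in_channels 2 for the dual fat+water input; 1 for the fat-only /
#'   water-only ablations.
#' @param out_channels number of class channels including background.
#' @param encoder_filters list of length-2 integer vectors, one per level.
#' @param bottleneck_filters length-2 integer vector.
#' @param input_size default in-plane training size `(rows, cols)`.
#' @param negative_slope LeakyReLU slope.
#' @param channels which input channels [predict.bodycomp_unet()] extracts
#'   from a [dual_volume()]: `"dual"`, `"fat"`, or `"water"`.
#' @param deep_supervision attach auxiliary 1x1 heads at decoder levels 2 and
#'   3 (half and quarter resolution) during training.
#' @return Object of class `net_config`.
#' @export
net_config <- function(in_channels = 2L,
                       out_channels = 5L,
                       encoder_filters = list(c(32L, 32L), c(64L, 64L),
                                              c(128L, 128L), c(256L, 256L),
                                              c(480L, 480L), c(480L, 480L)),
                       bottleneck_filters = c(480L, 480L),
                       input_size = c(512L, 512L),
                       negative_slope = 0.01,
                       channels = c("dual", "fat", "water"),
                       deep_supervision = TRUE) {
  channels <- match.arg(channels)
  if (channels != "dual" && in_channels != 1L)
    stop("single-sequence ablation requires in_channels = 1")
  if (channels == "dual" && in_channels != 2L)
    stop("dual input requires in_channels = 2")
  L <- length(encoder_filters)
  stopifnot(L >= 2L, out_channels >= 2L,
            all(vapply(encoder_filters, length, 1L) == 2L),
            length(bottleneck_filters) == 2L)
  div <- 2^L
  if (any(input_size %% div != 0))
    stop("input_size must be divisible by 2^", L)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 encoder_filters = lapply(encoder_filters, as.integer),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 input_size = as.integer(input_size),
                 negative_slope = negative_slope,
                 channels = channels,
                 deep_supervision = deep_supervision,
                 ds_levels = if (deep_supervision && L >= 3L) c(2L, 3L)
                             else integer(0)),
            class = "net_config")
}

#' @rdname net_config
#' @param region body region; sets `out_channels` (8 abdomen, 5 thigh).
#' @export
net_config_full <- function(region = c("abdomen", "thigh"), ...) {
  region <- match.arg(region)
  net_config(out_channels = if (region == "abdomen") 8L else 5L, ...)
}

#' @rdname net_config
#' @export
net_config_tiny <- function(region = c("abdomen", "thigh"),
                            input_size = c(64L, 64L), ...) {
  region <- match.arg(region)
  net_config(out_channels = if (region == "abdomen") 8L else 5L,
             encoder_filters = list(c(16L, 16L), c(32L, 32L),
                                    c(64L, 64L), c(64L, 64L)),
             bottleneck_filters = c(64L, 64L),
             input_size = input_size, ...)
}

# ordered list of parameterized layers: id, type (conv/upconv), kernel, cin, cout
unet_layer_plan <- function(config) {
  L <- length(config$encoder_filters)
  plan <- list()
  add <- function(id, type, k, cin, cout)
    plan[[length(plan) + 1L]] <<- list(id = id, type = type, k = k,
                                       cin = cin, cout = cout)
  cin <- config$in_channels
  for (l in seq_len(L)) {
    f <- config$encoder_filters[[l]]
    add(paste0("enc", l, ".c1"), "conv", 3L, cin, f[1])
    add(paste0("enc", l, ".c2"), "conv", 3L, f[1], f[2])
    cin <- f[2]
  }
  bf <- config$bottleneck_filters
  add("bott.c1", "conv", 3L, cin, bf[1])
  add("bott.c2", "conv", 3L, bf[1], bf[2])
  cin <- bf[2]
  for (l in rev(seq_len(L))) {
    f <- config$encoder_filters[[l]]
    add(paste0("dec", l, ".up"), "upconv", 2L, cin, f[2])
    skip <- config$encoder_filters[[l]][2]
    add(paste0("dec", l, ".c1"), "conv", 3L, f[2] + skip, f[1])
    add(paste0("dec", l, ".c2"), "conv", 3L, f[1], f[2])
    cin <- f[2]
  }
  add("head", "conv", 1L, config$encoder_filters[[1]][2], config$out_channels)
  for (r in config$ds_levels)
    add(paste0("ds", r), "conv", 1L,
        config$encoder_filters[[r]][2], config$out_channels)
  names(plan) <- vapply(plan, `[[`, "", "id")
  plan
}

#' Build a U-Net with He-initialized weights
#'
#' Weights are drawn from `N(0, sqrt(2 / fan_in))` (He initialization for
#' leaky-rectified layers; the 0.01 slope correction is negligible), biases
#' start at zero. Draws come from the current RNG stream.
#'
#' @param config a [net_config()].
#' @return Object of class `bodycomp_unet` with `config` and `params` (a
#'   named list of `W`/`b` pairs).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "net_config"))
  plan <- unet_layer_plan(config)
  params <- lapply(plan, function(ly) {
    fan_in <- ly$k^2 * ly$cin
    list(W = matrix(stats::rnorm(fan_in * ly$cout, 0, sqrt(2 / fan_in)),
                    fan_in, ly$cout),
         b = numeric(ly$cout))
  })
  structure(list(config = config, params = params, plan = plan, log = NULL),
            class = "bodycomp_unet")
}

#' Total trainable parameter count
#'
#' @param model a `bodycomp_unet`.
#' @param include_aux count the auxiliary deep-supervision heads too.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model, include_aux = TRUE) {
  ids <- names(model$params)
  if (!include_aux) ids <- ids[!startsWith(ids, "ds")]
  sum(vapply(ids, function(id)
    length(model$params[[id]]$W) + length(model$params[[id]]$b), numeric(1)))
}

lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
lrelu_grad <- function(pre, g, slope) {
  neg <- pre < 0
  g[neg] <- slope * g[neg]
  g
}

#' Forward pass of the U-Net on one slice
#'
#' Runs the network on a single `H x W x Cin` slice and returns the
#' unnormalized class score map. With `aux = TRUE` the auxiliary
#' deep-supervision score maps at coarser decoder resolutions are returned
#' too; `retain = TRUE` additionally keeps the activation cache needed for
#' backpropagation (training internals).
#'
#' @param model a `bodycomp_unet`.
#' @param x `H x W x Cin` numeric array, `H` and `W` divisible by
#'   `2^levels`.
#' @param retain keep activations for the backward pass.
#' @param aux compute auxiliary deep-supervision outputs.
#' @return list with `logits` (`H x W x out_channels`), `aux` (named list of
#'   coarser score maps), `bottleneck_dim` (spatial size of the deepest
#'   feature map), and `cache`.
#' @export
unet_forward <- function(model, x, retain = FALSE, aux = retain) {
  cfg <- model$config
  P <- model$params
  sl <- cfg$negative_slope
  L <- length(cfg$encoder_filters)
  cache <- if (retain) new.env(parent = emptyenv())
  keep <- function(id, val) if (retain) assign(id, val, envir = cache)
  conv_lr <- function(id, h) {
    keep(paste0(id, ".x"), h)
    pre <- .conv2d_fwd(h, P[[id]]$W, P[[id]]$b, model$plan[[id]]$k)
    keep(paste0(id, ".pre"), pre)
    lrelu(pre, sl)
  }
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    h <- conv_lr(paste0("enc", l, ".c1"), h)
    h <- conv_lr(paste0("enc", l, ".c2"), h)
    skips[[l]] <- h
    pooled <- .maxpool2_fwd(h)
    keep(paste0("pool", l, ".idx"), pooled$idx)
    keep(paste0("pool", l, ".dim"), dim(h))
    h <- pooled$y
  }
  bottleneck_dim <- dim(h)[1:2]
  h <- conv_lr("bott.c1", h)
  h <- conv_lr("bott.c2", h)
  aux_logits <- list()
  for (l in rev(seq_len(L))) {
    up_id <- paste0("dec", l, ".up")
    keep(paste0(up_id, ".x"), h)
    h <- .upconv2_fwd(h, P[[up_id]]$W, P[[up_id]]$b)
    keep(paste0("dec", l, ".nup"), dim(h)[3])
    h <- abind3(h, skips[[l]])
    h <- conv_lr(paste0("dec", l, ".c1"), h)
    h <- conv_lr(paste0("dec", l, ".c2"), h)
    if (aux && l %in% cfg$ds_levels) {
      ds_id <- paste0("ds", l)
      keep(paste0(ds_id, ".x"), h)
      aux_logits[[as.character(l)]] <-
        .conv2d_fwd(h, P[[ds_id]]$W, P[[ds_id]]$b, 1L)
    }
  }
  keep("head.x", h)
  logits <- .conv2d_fwd(h, P$head$W, P$head$b, 1L)
  list(logits = logits, aux = aux_logits, cache = cache,
       bottleneck_dim = bottleneck_dim)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# backprop: grad_logits (and optional named grad_aux, keyed by decoder level)
# -> named list of W/b gradients matching model$params.
unet_backward <- function(model, fwd, grad_logits, grad_aux = list()) {
  cfg <- model$config
  P <- model$params
  sl <- cfg$negative_slope
  L <- length(cfg$encoder_filters)
  cache <- fwd$cache
  grads <- list()
  conv_bwd <- function(id, gy) {
    pre <- get(paste0(id, ".pre"), envir = cache)
    gy <- lrelu_grad(pre, gy, sl)
    xin <- get(paste0(id, ".x"), envir = cache)
    r <- .conv2d_bwd(xin, P[[id]]$W, gy, model$plan[[id]]$k)
    grads[[id]] <<- list(W = r$gW, b = as.numeric(r$gb))
    r$gx
  }
  # head (linear 1x1)
  head_x <- get("head.x", envir = cache)
  r <- .conv2d_bwd(head_x, P$head$W, grad_logits, 1L)
  grads$head <- list(W = r$gW, b = as.numeric(r$gb))
  g <- r$gx
  add_aux <- function(g, l) {
    # inject the auxiliary deep-supervision head's gradient at this level
    ga <- grad_aux[[as.character(l)]]
    if (is.null(ga)) return(g)
    ds_id <- paste0("ds", l)
    xa <- get(paste0(ds_id, ".x"), envir = cache)
    ra <- .conv2d_bwd(xa, P[[ds_id]]$W, ga, 1L)
    grads[[ds_id]] <<- list(W = ra$gW, b = as.numeric(ra$gb))
    g + ra$gx
  }
  for (l in seq_len(L)) {
    # decoder level l (finest to coarsest, reverse of the forward pass)
    g <- add_aux(g, l)
    g <- conv_bwd(paste0("dec", l, ".c2"), g)
    g <- conv_bwd(paste0("dec", l, ".c1"), g)
    nup <- get(paste0("dec", l, ".nup"), envir = cache)
    g_up <- g[, , seq_len(nup), drop = FALSE]
    g_skip <- g[, , nup + seq_len(dim(g)[3] - nup), drop = FALSE]
    up_id <- paste0("dec", l, ".up")
    xin <- get(paste0(up_id, ".x"), envir = cache)
    ru <- .upconv2_bwd(xin, P[[up_id]]$W, g_up)
    grads[[up_id]] <- list(W = ru$gW, b = as.numeric(ru$gb))
    g <- ru$gx
    # stash skip gradient for the encoder walk
    assign(paste0("gskip", l), g_skip, envir = cache)
  }
  # bottleneck
  g <- conv_bwd("bott.c2", g)
  g <- conv_bwd("bott.c1", g)
  # encoder from deepest to shallowest
  for (l in rev(seq_len(L))) {
    dims <- get(paste0("pool", l, ".dim"), envir = cache)
    idx <- get(paste0("pool", l, ".idx"), envir = cache)
    g <- .maxpool2_bwd(idx, g, dims[1], dims[2])
    g <- g + get(paste0("gskip", l), envir = cache)
    g <- conv_bwd(paste0("enc", l, ".c2"), g)
    g <- conv_bwd(paste0("enc", l, ".c1"), g)
  }
  grads
}

#' Slice-wise segmentation of a volume
#'
#' Runs the 2D model on every axial slice, applies a per-pixel softmax and
#' takes the argmax class (ties broken toward the lower class id), and
#' restacks the slices into a mask with the volume's geometry. Output channel
#' 1 is background; channel `c` maps to label id `c - 1`.
#'
#' @param model a `bodycomp_unet`.
#' @param volume a preprocessed [dual_volume()] whose in-plane size is
#'   divisible by `2^levels`.
#' @param schema [label_schema()] for the output mask.
#' @return A [label_mask()].
#' @export
predict_volume <- function(model, volume, schema) {
  stopifnot(inherits(model, "bodycomp_unet"), inherits(volume, "dual_volume"))
  cfg <- model$config
  d <- dim(volume$fat)
  L <- length(cfg$encoder_filters)
  if (any(d[1:2] %% 2^L != 0))
    stop("in-plane size must be divisible by 2^", L)
  if (cfg$out_channels != length(schema$label_ids) + 1L)
    stop("schema has ", length(schema$label_ids),
         " labels but the model emits ", cfg$out_channels, " channels")
  out <- array(0L, d)
  for (s in seq_len(d[3])) {
    x <- slice_channels(volume, s, cfg)
    logits <- unet_forward(model, x, retain = FALSE, aux = FALSE)$logits
    out[, , s] <- apply(logits, c(1, 2), which.max) - 1L
  }
  label_mask(out, schema, volume$spacing)
}

# extract the configured input channels of one slice as H x W x Cin
slice_channels <- function(volume, s, cfg) {
  d <- dim(volume$fat)
  switch(cfg$channels,
    dual = {
      x <- array(0, c(d[1], d[2], 2L))
      x[, , 1] <- volume$fat[, , s]
      x[, , 2] <- volume$water[, , s]
      x
    },
    fat = array(volume$fat[, , s], c(d[1], d[2], 1L)),
    water = array(volume$water[, , s], c(d[1], d[2], 1L))
  )
}

#' @export
print.bodycomp_unet <- function(x, ...) {
  cfg <- x$config
  L <- length(cfg$encoder_filters)
  cat(sprintf("bodycomp_unet: %d-level dual 2D U-Net (%s input, %d -> %d channels)\n",
              L, cfg$channels, cfg$in_channels, cfg$out_channels))
  cat(sprintf("  filters: %s; bottleneck (%d,%d)\n",
              paste(vapply(cfg$encoder_filters,
                           function(f) sprintf("(%d,%d)", f[1], f[2]), ""),
                    collapse = ", "),
              cfg$bottleneck_filters[1], cfg$bottleneck_filters[2]))
  cat(sprintf("  parameters: %s\n", format(n_parameters(x), big.mark = ",")))
  if (!is.null(x$log))
    cat(sprintf("  trained: %d epochs, final loss %.4f\n",
                nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.bodycomp_unet <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("training log (last 5 epochs):\n")
    print(utils::tail(object$log, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.bodycomp_unet <- function(x, ...) {
  if (is.null(x$log)) stop("model has no training log")
  graphics::plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "bodycomp_unet training", ...)
  if (any(!is.na(x$log$val_dsc))) {
    graphics::par(new = TRUE)
    graphics::plot(x$log$epoch, x$log$val_dsc, type = "l", col = "red",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "red")
    graphics::mtext("validation DSC", side = 4, line = 2, col = "red")
  }
  invisible(x)
}

#' Predict method: segment a dual volume
#'
#' @param object a trained `bodycomp_unet`.
#' @param volume a [dual_volume()].
#' @param schema a [label_schema()]; defaults to the region matching the
#'   model's output channel count.
#' @param ... unused.
#' @return A [label_mask()].
#' @export
predict.bodycomp_unet <- function(object, volume, schema = NULL, ...) {
  if (is.null(schema)) {
    schema <- if (object$config$out_channels == 8L) label_schema("abdomen")
              else label_schema("thigh")
  }
  predict_volume(object, volume, schema)
}
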