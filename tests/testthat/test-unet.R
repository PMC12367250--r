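test_that("shape contract holds and the full preset bottlenecks at 8x8", {
  # tiny preset at its native 64x64
  set.seed(1)
  tiny <- build_unet(net_config_tiny("thigh"))
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  f <- unet_forward(tiny, x)
  expect_identical(dim(f$logits), c(64L, 64L, 5L))
  expect_identical(f$bottleneck_dim, c(4L, 4L))
  # shape contract for another divisible size
  x96 <- array(rnorm(96 * 96 * 2), c(96, 96, 2))
  expect_identical(dim(unet_forward(tiny, x96)$logits), c(96L, 96L, 5L))
  # full preset: (2,512,512) -> (out,512,512) with an 8x8 bottleneck
  set.seed(2)
  full <- build_unet(net_config_full("thigh", deep_supervision = FALSE))
  xf <- array(rnorm(512 * 512 * 2), c(512, 512, 2))
  ff <- unet_forward(full, xf, retain = FALSE, aux = FALSE)
  expect_identical(dim(ff$logits), c(512L, 512L, 5L))
  expect_identical(ff$bottleneck_dim, c(8L, 8L))
  rm(full, ff); gc(FALSE)
})

test_that("parameter count equals the layer-arithmetic oracle", {
  # oracle: sum over the declared layer list of k^2 * c_in * c_out + c_out,
  # written out from the architecture definition, independent of the builder
  oracle_count <- function(in_ch, out_ch, enc, bott, ds_levels) {
    total <- 0
    cin <- in_ch
    for (f in enc) {
      total <- total + 9 * cin * f[1] + f[1] + 9 * f[1] * f[2] + f[2]
      cin <- f[2]
    }
    total <- total + 9 * cin * bott[1] + bott[1] + 9 * bott[1] * bott[2] + bott[2]
    cin <- bott[2]
    for (l in rev(seq_along(enc))) {
      f <- enc[[l]]
      total <- total + 4 * cin * f[2] + f[2]            # 2x2 transposed conv
      total <- total + 9 * (2 * f[2]) * f[1] + f[1]     # conv on concat
      total <- total + 9 * f[1] * f[2] + f[2]
      cin <- f[2]
    }
    total <- total + 1 * enc[[1]][2] * out_ch + out_ch  # 1x1 head
    for (l in ds_levels)
      total <- total + enc[[l]][2] * out_ch + out_ch    # aux heads
    total
  }
  full_enc <- list(c(32, 32), c(64, 64), c(128, 128), c(256, 256),
                   c(480, 480), c(480, 480))
  set.seed(3)
  m <- build_unet(net_config_full("abdomen"))
  expect_equal(n_parameters(m),
                   oracle_count(2, 8, full_enc, c(480, 480), c(2, 3)))
  tiny_enc <- list(c(16, 16), c(32, 32), c(64, 64), c(64, 64))
  mt <- build_unet(net_config_tiny("thigh"))
  expect_equal(n_parameters(mt),
                   oracle_count(2, 5, tiny_enc, c(64, 64), c(2, 3)))
  # ablation variants differ only in the first conv's input channels
  mf <- build_unet(net_config_tiny("thigh", in_channels = 1L,
                                   channels = "fat"))
  expect_equal(n_parameters(mt) - n_parameters(mf), 9 * 1 * 16)
})

test_that("invalid input sizes and channel mismatches error", {
  expect_error(net_config_tiny("thigh", input_size = c(60L, 60L)),
               "divisible")
  set.seed(4)
  m <- build_unet(net_config_tiny("thigh"))
  cs <- generate_phantom(thigh_params(grid = c(8, 40, 40)))  # 40 % 16 != 0
  expect_error(predict_volume(m, cs$volume, cs$truth$schema), "divisible")
  cs32 <- generate_phantom(thigh_params(grid = c(8, 32, 32)))
  expect_error(predict_volume(m, cs32$volume, label_schema("abdomen")),
               "channels")
})

test_that("argmax decoding ties break toward the lower class id", {
  # zero all weights: logits identically zero, everything ties -> class 1
  set.seed(5)
  m <- build_unet(net_config_tiny("thigh"))
  for (id in names(m$params)) {
    m$params[[id]]$W[] <- 0
    m$params[[id]]$b[] <- 0
  }
  cs <- generate_phantom(thigh_params(grid = c(8, 32, 32)))
  pred <- predict_volume(m, cs$volume, cs$truth$schema)
  expect_true(all(pred$labels == 0L))  # background = lowest class id
})

test_that("injected one-hot scores decode to the encoded labels", {
  sch <- label_schema("thigh")
  set.seed(6)
  lab <- matrix(sample(0:4, 32 * 32, TRUE), 32, 32)
  logits <- array(0, c(32, 32, 5))
  for (k in 1:5) logits[, , k] <- (lab == k - 1) * 10
  dec <- apply(logits, c(1, 2), which.max) - 1L
  expect_identical(dec, lab)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(12)
  cfg <- net_config(in_channels = 2, out_channels = 3,
                    encoder_filters = list(c(4L, 4L), c(4L, 4L), c(6L, 6L)),
                    bottleneck_filters = c(6L, 6L), input_size = c(16L, 16L))
  m <- build_unet(cfg)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  y <- matrix(sample(0:2, 256, TRUE), 16, 16)
  w <- c(4, 2, 1) / 7
  total_loss <- function(model) {
    f <- unet_forward(model, x, retain = FALSE, aux = TRUE)
    l <- w[1] * composite_loss(f$logits, y)$loss
    l <- l + w[2] * composite_loss(f$aux[["2"]],
                                   y[seq(1, 16, 2), seq(1, 16, 2)])$loss
    l + w[3] * composite_loss(f$aux[["3"]],
                              y[seq(1, 16, 4), seq(1, 16, 4)])$loss
  }
  f <- unet_forward(m, x, retain = TRUE, aux = TRUE)
  g_top <- composite_loss(f$logits, y, grad = TRUE)
  g2 <- composite_loss(f$aux[["2"]], y[seq(1, 16, 2), seq(1, 16, 2)],
                       grad = TRUE)
  g3 <- composite_loss(f$aux[["3"]], y[seq(1, 16, 4), seq(1, 16, 4)],
                       grad = TRUE)
  grads <- unet_backward(m, f, w[1] * g_top$dscore,
                         list("2" = w[2] * g2$dscore, "3" = w[3] * g3$dscore))
  eps <- 1e-6
  for (id in c("enc1.c1", "enc2.c2", "bott.c1", "dec3.up", "dec1.c2",
               "ds2", "ds3", "head")) {
    i <- sample(length(m$params[[id]]$W), 1)
    mp <- m; mp$params[[id]]$W[i] <- mp$params[[id]]$W[i] + eps
    mm <- m; mm$params[[id]]$W[i] <- mm$params[[id]]$W[i] - eps
    num <- (total_loss(mp) - total_loss(mm)) / (2 * eps)
    expect_equal(grads[[id]]$W[i], num, tolerance = 1e-4)
  }
})

test_that("convolution plumbing is mirror-equivariant for symmetric kernels", {
  # a single 3x3 conv with a left-right symmetric kernel commutes with
  # column mirroring; an asymmetric kernel does not
  set.seed(13)
  x <- array(rnorm(12 * 12), c(12, 12, 1))
  sym <- matrix(0, 9, 1)
  sym[, 1] <- c(1, 2, 1, 0, 3, 0, 1, 2, 1)  # symmetric in kx
  y <- bodycomp:::.conv2d_fwd(x, sym, 0, 3L)
  xm <- x[, 12:1, , drop = FALSE]
  ym <- bodycomp:::.conv2d_fwd(xm, sym, 0, 3L)
  expect_equal(ym[, 12:1, , drop = FALSE], y, tolerance = 1e-12)
  asym <- sym; asym[1, 1] <- 9
  ya <- bodycomp:::.conv2d_fwd(x, asym, 0, 3L)
  yam <- bodycomp:::.conv2d_fwd(xm, asym, 0, 3L)
  expect_gt(max(abs(yam[, 12:1, , drop = FALSE] - ya)), 1e-6)
})
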