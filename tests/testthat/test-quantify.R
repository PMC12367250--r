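test_that("volumes are voxel count times voxel volume", {
  sch <- label_schema("thigh")
  arr <- array(0L, c(10, 10, 10)); arr[1:10, 1:10, 1:10] <- 4L
  m <- label_mask(arr, sch, c(1, 1, 1))
  expect_equal(volume_of(m, "muscle"), 1.0)   # 1000 unit voxels = 1 mL
  one <- array(0L, c(8, 8, 8)); one[1, 1, 1] <- 1L
  m2 <- label_mask(one, sch, c(10, 0.82, 0.82))
  expect_equal(volume_of(m2, "femur"), 0.82 * 0.82 * 10 / 1000,
               tolerance = 1e-12)
})

test_that("volume quantification ignores relabeling of other compartments", {
  cs <- generate_phantom(thigh_params(grid = c(8, 32, 32)))
  v1 <- volume_of(cs$truth, "muscle")
  swapped <- cs$truth$labels
  swapped[swapped == 1L] <- 99L; swapped[swapped == 2L] <- 1L
  swapped[swapped == 99L] <- 2L  # permute femur and vessel
  m <- label_mask(swapped, cs$truth$schema, cs$truth$spacing)
  expect_equal(volume_of(m, "muscle"), v1)
})

test_that("circumference recovers analytic shapes within convention error", {
  sch <- label_schema("thigh")
  # digitized circle, radius 50 px at 1 mm: within 2% of 2*pi*50
  n <- 128
  z <- outer(1:n, 1:n, function(i, j)
    as.integer((i - 64.5)^2 + (j - 64.5)^2 <= 50^2))
  m <- label_mask(array(z, c(n, n, 1)), sch, c(1, 1, 1))
  circ <- circumference_of(m, "femur")
  expect_lt(abs(circ - 2 * pi * 50) / (2 * pi * 50), 0.02)
  # axis-aligned 10x10 square: 40 mm minus the documented corner rounding
  zq <- array(0L, c(32, 32, 1)); zq[11:20, 11:20, 1] <- 1L
  mq <- label_mask(zq, sch, c(1, 1, 1))
  cq <- circumference_of(mq, "femur")
  expect_lt(cq, 40)
  expect_gt(cq, 40 - 4.5)  # corner rounding removes < ~1.1 px per corner
  # linearity in spacing: doubling spacing doubles the result
  m2 <- label_mask(zq, sch, c(1, 2, 2))
  expect_equal(circumference_of(m2, "femur"), 2 * cq, tolerance = 1e-9)
})

test_that("circumference uses the largest connected component per slice", {
  sch <- label_schema("thigh")
  z <- array(0L, c(64, 64, 1))
  z[20:40, 20:40, 1] <- 1L   # large block
  z[5:6, 5:6, 1] <- 1L       # stray small component
  m <- label_mask(z, sch, c(1, 1, 1))
  z2 <- z; z2[5:6, 5:6, 1] <- 0L
  m2 <- label_mask(z2, sch, c(1, 1, 1))
  expect_equal(circumference_of(m, "femur"), circumference_of(m2, "femur"))
  empty <- label_mask(array(0L, c(8, 8, 1)), sch, c(1, 1, 1))
  expect_error(circumference_of(empty, "femur"), "empty")
})

test_that("1-D 2-means separates well-separated modes exactly", {
  x <- array(c(rep(100, 80), rep(1000, 20)), c(10, 10, 1))
  mask <- array(TRUE, c(10, 10, 1))
  km <- kmeans_imat(x, mask, seed = 3)
  expect_equal(km$centers, c(100, 1000))
  expect_identical(sum(km$imat_mask), 20L)
  expect_true(all(x[km$imat_mask] == 1000))
  # constant intensities: degenerate, fraction 0
  kc <- kmeans_imat(array(7, c(5, 5, 1)), array(TRUE, c(5, 5, 1)))
  expect_true(kc$degenerate)
  expect_equal(imat_percentage(kc, array(TRUE, c(5, 5, 1))), 0)
  expect_error(kmeans_imat(x, array(FALSE, c(10, 10, 1))), "empty")
})

test_that("Lloyd 2-means matches the exhaustive threshold-search optimum", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(200:2000, 1)
    x <- c(rnorm(n, 100, 30), rnorm(round(n / 3), 900, 60))
    arr <- array(x, c(length(x), 1, 1))
    mask <- array(TRUE, dim(arr))
    km <- kmeans_imat(arr, mask, seed = rep)
    ex <- threshold_2means(x)
    # same partition: the Lloyd solution reaches the global threshold optimum
    expect_identical(which(km$imat_mask), which(arr > ex$threshold))
    expect_equal(sort(km$centers), sort(ex$centers), tolerance = 1e-6)
  }
})

test_that("threshold search against stats::kmeans on small inputs", {
  set.seed(5)
  x <- c(rnorm(300, 10, 3), rnorm(150, 40, 4))
  ex <- threshold_2means(x)
  ref <- stats::kmeans(x, centers = sort(ex$centers), iter.max = 100)
  expect_equal(ex$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("planted IMAT fraction is recovered on noiseless phantoms", {
  for (f in c(0.05, 0.20)) {
    cs <- generate_phantom(thigh_params(imat = f, noise_sd = 0))
    mus <- cs$truth$labels == 4L
    km <- kmeans_imat(cs$volume$fat, mus, seed = 1)
    rec <- imat_percentage(km, mus) / 100
    expect_lt(abs(rec - f), 0.02)
    # and against the planted truth exactly at zero noise
    expect_identical(which(km$imat_mask), which(cs$imat_truth))
  }
})

test_that("grade bins threshold monotonically", {
  expect_identical(grade_bins(0), 0L)
  expect_identical(grade_bins(10, c(5, 25)), 1L)
  expect_identical(grade_bins(30, c(5, 25)), 2L)
  ps <- seq(0, 60, by = 2.5)
  g <- grade_bins(ps)
  expect_true(all(diff(g) >= 0))
  expect_error(grade_bins(1, c(10, 5)))
})

test_that("composition profile matches the reference profile on phantoms", {
  cs <- generate_phantom(abdomen_params(grid = c(8, 64, 64), noise_sd = 0))
  prof <- composition_profile(cs$volume, cs$truth, seed = 2)
  ref <- reference_profile(cs)
  expect_equal(prof$volumes_ml, ref$volumes_ml, tolerance = 1e-12)
  expect_equal(prof$imat_fraction, ref$imat_fraction, tolerance = 0.02)
  # merge identities hold exactly
  v <- prof$volumes_ml
  expect_equal(v[["SAT"]], v[["sSAT"]] + v[["dSAT"]], tolerance = 1e-12)
  expect_equal(v[["VAT"]], v[["IPAT"]] + v[["RPAT"]], tolerance = 1e-12)
  # IMAT clustering is scoped to the core muscle: planted speckle lives there
  expect_true(all(cs$truth$labels[prof$imat_mask] == 3L))
})
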