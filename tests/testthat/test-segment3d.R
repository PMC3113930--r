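# Histograms, valley/Otsu/half-max thresholds, 2x2x2 downsampling, and
# 3D connected-component labelling.

test_that("grey histogram conserves counts and spans the value range", {
  v <- volume3d(array(rep(c(0, 1), each = 500), c(10, 10, 10)), 1)
  h <- grey_histogram(v, n_bins = 16)
  expect_equal(sum(h$counts), 1000)
  expect_equal(h$counts[1], 500)
  expect_equal(h$counts[16], 500)
  expect_error(grey_histogram(volume3d(array(1, c(4, 4, 4)), 1)), "constant")
  expect_error(grey_histogram(v, n_bins = 8), "n_bins")
})

test_that("valley threshold separates well-separated modes", {
  set.seed(1)
  v1 <- volume3d(array(c(rnorm(5e4), rnorm(5e4, 10)), c(10, 100, 100)), 1)
  t1 <- valley_threshold(grey_histogram(v1))
  expect_gt(t1, 4); expect_lt(t1, 6)
  v2 <- volume3d(array(c(rnorm(9e4), rnorm(1e4, 10)), c(10, 100, 100)), 1)
  t2 <- valley_threshold(grey_histogram(v2))
  expect_gt(t2, 3); expect_lt(t2, 7)
})

test_that("valley threshold breaks plateau ties toward the lower grey value", {
  # all mass in two spikes; the flat zero valley between them must resolve
  # to its lowest bin
  vals <- c(rep(2, 400), rep(9, 400), 0, 12)  # sentinels pin the range
  v <- volume3d(array(vals, c(1, 1, length(vals))), 1)
  h <- grey_histogram(v, n_bins = 16)
  thr <- valley_threshold(h)
  cen <- (head(h$bin_edges, -1) + tail(h$bin_edges, -1)) / 2
  # independent brute force: smallest smoothed count strictly between the
  # two modes, lowest bin on ties
  expect_lt(thr, (2 + 9) / 2)   # tie resolved low
  expect_gt(thr, 2); expect_lt(thr, 9)
})

test_that("valley threshold rejects unimodal histograms", {
  set.seed(2)
  v <- volume3d(array(rnorm(1e4), c(10, 10, 100)), 1)
  expect_error(valley_threshold(grey_histogram(v)), "not bimodal")
})

test_that("otsu matches a brute-force between-class-variance scan", {
  set.seed(3)
  vals <- c(rnorm(3000, 0, 0.5), rnorm(1500, 6, 0.8))
  v <- volume3d(array(vals, c(10, 10, 45)), 1)
  got <- otsu_threshold(v, n_bins = 16)
  # independent exhaustive oracle over the same 16-bin histogram
  lo <- min(vals); hi <- max(vals)
  edges <- seq(lo, hi, length.out = 17)
  idx <- pmin(floor((vals - lo) / (hi - lo) * 16) + 1, 16)
  counts <- tabulate(idx, 16)
  centres <- (head(edges, -1) + tail(edges, -1)) / 2
  best <- -Inf; best_t <- NA
  for (t in 1:15) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:t] * centres[1:t]) / w0
    m1 <- sum(counts[(t + 1):16] * centres[(t + 1):16]) / w1
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best) { best <- bcv; best_t <- edges[t + 1] }
  }
  expect_equal(got, best_t, tolerance = 1e-12)
  # strictly between the two classes of a binary volume
  vb <- volume3d(array(rep(c(0, 1), each = 500), c(10, 10, 10)), 1)
  tb <- otsu_threshold(vb)
  expect_gt(tb, 0); expect_lt(tb, 1)
})

test_that("otsu threshold maps through affine intensity rescaling", {
  set.seed(4)
  vals <- c(rnorm(2000), rnorm(1000, 8))
  v <- volume3d(array(vals, c(10, 10, 30)), 1)
  t0 <- otsu_threshold(v)
  v2 <- v; v2$values <- 3 * v$values - 5
  expect_equal(otsu_threshold(v2), 3 * t0 - 5, tolerance = 1e-9)
})

test_that("smooth_downsample averages 2x2x2 blocks and doubles the voxel", {
  const <- volume3d(array(2.5, c(8, 8, 8)), 0.5)
  d <- smooth_downsample(const)
  expect_true(all(d$values == 2.5))
  expect_equal(d$voxel_size, 1.0)
  expect_equal(dim(d$values), c(4L, 4L, 4L))
  # 3D checkerboard averages to exactly one half
  idx <- expand.grid(z = 1:8, y = 1:8, x = 1:8)
  chk <- array((idx$z + idx$y + idx$x) %% 2, c(8, 8, 8))
  dc <- smooth_downsample(volume3d(chk, 1))
  expect_true(all(dc$values == 0.5))
  # block means conserve total mass exactly on even dimensions
  set.seed(5)
  r <- volume3d(array(runif(512), c(8, 8, 8)), 1)
  dr <- smooth_downsample(r)
  expect_equal(sum(dr$values) * 8, sum(r$values), tolerance = 1e-12)
  expect_message(smooth_downsample(volume3d(array(0:124, c(5, 5, 5)), 1)),
                 "dropping odd")
  expect_error(smooth_downsample(volume3d(array(1:4, c(1, 2, 2)), 1)), ">= 2")
})

test_that("labelling counts, despeckles, excludes borders and orders by size", {
  v <- array(0, c(40, 40, 40))
  fill_ball <- function(v, c, r) {
    idx <- which(array(TRUE, dim(v)), arr.ind = TRUE)
    d2 <- (idx[, 1] - c[1])^2 + (idx[, 2] - c[2])^2 + (idx[, 3] - c[3])^2
    v[d2 <= r^2] <- 1
    v
  }
  v <- fill_ball(v, c(12, 12, 12), 7)
  v <- fill_ball(v, c(30, 30, 30), 4)
  v[1, 1, 40] <- 1                      # speckle
  vol <- volume3d(v, 1)
  lab <- label_components(vol, 0.5)
  expect_equal(n_labels(lab), 2L)
  expect_true(all(diff(lab$sizes) <= 0))  # size-descending labels
  # despeckling off keeps the lone voxel
  lab3 <- label_components(vol, 0.5, min_voxels = 1)
  expect_equal(n_labels(lab3), 3L)
  # a ball touching the z = 0 face disappears under border exclusion
  vb <- array(0, c(20, 20, 20))
  vb <- fill_ball(vb, c(1, 10, 10), 5)
  expect_error(label_components(volume3d(vb, 1), 0.5, exclude_border = TRUE),
               "no components remain")
  expect_error(label_components(vol, 2), "outside")
  expect_error(label_components(volume3d(array(0, c(4, 4, 4)) + 0.1, 1), 0.1,
                                min_voxels = 200), "no components remain")
})
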