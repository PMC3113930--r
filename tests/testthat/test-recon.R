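# WBP / SIRT / ART reconstruction, missing-wedge behaviour and quality
# metrics.  Full-range and wedge-limited series of a known sphere phantom
# serve as the oracle.

sphere_bench <- local({
  cache <- new.env()
  function(tilt = 90, noisy = FALSE, increment = 2) {
    key <- paste(tilt, noisy, increment)
    if (is.null(cache[[key]])) {
      ph <- fix_sphere(diameter = 32, voxel = 1, n = 64)
      pars <- acquisition_params(tilt_min = -tilt, tilt_max = tilt,
                                 increment = increment, jitter_max = 0,
                                 dose = 2000, seed = 3)
      ts <- project_series(ph$volume, pars)
      if (noisy) ts <- add_noise(ts, pars)
      cache[[key]] <- list(phantom = ph, series = ts)
    }
    cache[[key]]
  }
})

test_that("WBP centres a point impulse and matches the phantom on full-range data", {
  v <- array(0, c(48, 48, 48))
  v[25, 25, 25] <- 1
  ts <- project_series(volume3d(v, 1),
                       acquisition_params(tilt_min = -89, tilt_max = 90,
                                          increment = 1, jitter_max = 0))
  rec <- wbp(ts)
  expect_equal(which.max(rec$values), which.max(v))
  bench <- sphere_bench(90)
  q <- reconstruction_quality(wbp(bench$series), bench$phantom$volume)
  expect_gte(q$pearson_r, 0.95)
})

test_that("SIRT exceeds 0.98 correlation on noise-free full-range data", {
  bench <- sphere_bench(90)
  rec <- sirt(bench$series, n_iter = 15)
  q <- reconstruction_quality(rec, bench$phantom$volume)
  expect_gte(q$pearson_r, 0.98)
  # residual norms strictly decreasing on consistent data
  res <- attr(rec, "residual_norms")
  expect_true(all(diff(res) < 0))
})

test_that("ART matches the phantom and is deterministic", {
  bench <- sphere_bench(90)
  rec <- art(bench$series, n_iter = 10)
  q <- reconstruction_quality(rec, bench$phantom$volume)
  expect_gte(q$pearson_r, 0.95)
  rec2 <- art(bench$series, n_iter = 10)
  expect_identical(rec$values, rec2$values)
})

test_that("ART converges to consistency with a single projection", {
  bench <- sphere_bench(90)
  one <- tilt_series(bench$series$images[, , 46, drop = FALSE],
                     bench$series$angles[46], 1)
  # masking would clip the back-smeared corners this one-equation system
  # legitimately uses
  rec <- art(one, n_iter = 30, relax = 1, mask_fov = FALSE)
  reproj <- cpp_project(rec$values, dim(rec$values), one$angles, 0, 1)
  rel <- sqrt(sum((reproj - one$images)^2) / sum(one$images^2))
  expect_lt(rel, 0.01)
})

test_that("missing wedge produces z-elongation that grows as the range shrinks", {
  z90 <- reconstruction_quality(sirt(sphere_bench(90)$series, 10),
                                sphere_bench(90)$phantom$volume)$z_elongation
  z65 <- reconstruction_quality(sirt(sphere_bench(65)$series, 10),
                                sphere_bench(65)$phantom$volume)$z_elongation
  z50 <- reconstruction_quality(sirt(sphere_bench(50)$series, 10),
                                sphere_bench(50)$phantom$volume)$z_elongation
  expect_gte(z65, 1.0)
  expect_lt(abs(z90 - 1), 0.1)
  expect_gte(z50, z65)
  expect_gte(z65, z90)
})

test_that("SIRT beats WBP in SNR on the noisy wedge-limited benchmark", {
  bench <- sphere_bench(65, noisy = TRUE)
  truth <- bench$phantom$volume
  snr_sirt <- reconstruction_quality(sirt(bench$series, 15), truth)$snr_db
  snr_wbp <- reconstruction_quality(wbp(bench$series), truth)$snr_db
  expect_gte(snr_sirt, snr_wbp)
})

test_that("reconstruction operators are linear in the input", {
  bench <- sphere_bench(65)
  ts2 <- bench$series
  ts2$images <- 2 * ts2$images
  w1 <- wbp(bench$series)$values
  w2 <- wbp(ts2)$values
  expect_equal(w2, 2 * w1, tolerance = 1e-10)
  s1 <- sirt(bench$series, 5)$values
  s2 <- sirt(ts2, 5)$values
  expect_equal(s2, 2 * s1, tolerance = 1e-8)
})

test_that("reconstruction_quality reports identity, known noise and guards", {
  ph <- fix_sphere(diameter = 16, voxel = 1, n = 32)
  q <- reconstruction_quality(ph$volume, ph$volume)
  expect_equal(q$pearson_r, 1.0)
  expect_equal(q$snr_db, 99)
  set.seed(42)
  noisy <- ph$volume
  sigma <- 0.1
  noisy$values <- noisy$values + array(rnorm(length(noisy$values), 0, sigma),
                                       dim(noisy$values))
  qn <- reconstruction_quality(noisy, ph$volume)
  # affine matching attenuates independent noise, so the residual variance
  # is sigma^2 * var_t / (var_t + sigma^2) and the SNR closed form follows
  var_t <- var(as.numeric(ph$volume$values))
  expected_db <- 10 * log10(1 + var_t / sigma^2)
  expect_lt(abs(qn$snr_db - expected_db), 0.5)
  small <- volume3d(array(0:7 / 7, c(2, 2, 2)), 1)
  expect_error(reconstruction_quality(ph$volume, small), "mismatch")
})

test_that("iteration settings are validated", {
  bench <- sphere_bench(90)
  expect_error(sirt(bench$series, relax = 1.5), "relax")
  expect_error(sirt(bench$series, n_iter = 0), "n_iter")
  expect_error(art(bench$series, relax = 0), "relax")
})
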