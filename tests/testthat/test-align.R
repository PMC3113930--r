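# Cross-correlation registration, chain alignment with gauge fixing, and
# tilt-axis offset refinement.

test_that("register_pair recovers integer and subpixel shifts", {
  ph <- fix_sphere(diameter = 20, voxel = 1, n = 48)
  ts <- project_series(ph$volume, fix_params(jitter_max = 0))
  img <- ts$images[, , zero_tilt_index(ts)]
  expect_equal(unname(register_pair(img, img)), c(0, 0), tolerance = 1e-6)
  shifted <- cpp_shift_image(img, 3, -2)
  expect_equal(unname(register_pair(img, shifted)), c(3, -2), tolerance = 0.25)
  sub <- cpp_shift_image(img, 1.5, 0.5)
  expect_equal(unname(register_pair(img, sub)), c(1.5, 0.5), tolerance = 0.25)
  expect_error(register_pair(matrix(1, 8, 8), matrix(1, 8, 8)), "constant")
  expect_error(register_pair(img, img[1:10, 1:10]), "equal shapes")
})

# project the truth shifts onto the observable complement of the alignment
# gauge: constant in y; constant + sin + cos (object translation) in x
gauge_project <- function(shifts, angles) {
  th <- angles * pi / 180
  basis <- cbind(1, sin(th), cos(th))
  cbind(shifts[, 1] - mean(shifts[, 1]),
        stats::lm.fit(basis, shifts[, 2])$residuals)
}

test_that("alignment recovers applied jitter within 0.5 px RMS", {
  fx <- fix_sphere_series(n_spheres = 4, diameter = 18, grid = 80, seed = 21,
                          params = fix_params(dose = 0, jitter_max = 0,
                                              increment = 1))
  pars <- acquisition_params(jitter_max = 4, dose = 2000, seed = 11,
                             increment = 1)
  jittered <- apply_jitter(fx$series, pars)
  noisy <- add_noise(jittered, pars)
  for (ts in list(jittered, noisy)) {
    al <- align_series(ts)
    est <- al$result$shifts
    tru <- gauge_project(ts$applied_shifts, ts$angles)
    expect_lt(sqrt(mean((est - tru)^2)), 0.5)
    expect_true(al$result$converged)
  }
})

test_that("already-aligned series converges immediately and alignment is idempotent", {
  # a centred particle: the registration chain sees no geometric drift
  ph <- fix_sphere(diameter = 20, voxel = 1, n = 64)
  centred <- project_series(ph$volume, fix_params(jitter_max = 0))
  al <- align_series(centred)
  expect_equal(al$result$n_iterations, 1L)
  expect_lt(max(abs(al$result$shifts)), 0.5)
  # aligning an aligned series changes shifts by < tol
  fx <- fix_sphere_series(n_spheres = 3, diameter = 18, grid = 64)
  pars <- acquisition_params(jitter_max = 3, seed = 5, increment = 2)
  jit <- apply_jitter(fx$series, pars)
  first <- align_series(jit)
  second <- align_series(first$series)
  expect_lt(mean(sqrt(rowSums(second$result$shifts^2))), 0.5)
})

test_that("residual history is non-increasing after the first iteration", {
  fx <- fix_sphere_series(n_spheres = 4, diameter = 18, grid = 64, seed = 9)
  pars <- acquisition_params(jitter_max = 4, seed = 13, increment = 2)
  jit <- apply_jitter(fx$series, pars)
  al <- align_series(jit, tol = 0.05, max_iter = 6)
  h <- al$result$residual_history
  if (length(h) > 1) expect_true(all(diff(h) <= 1e-6))
})

test_that("tilt-axis refinement recovers known offsets", {
  ph <- fix_sphere(diameter = 20, voxel = 1, n = 64)
  pars <- fix_params(jitter_max = 0)
  ts0 <- project_series(ph$volume, pars, axis_offset = 0)
  expect_lt(abs(refine_tilt_axis(ts0)), 0.5)
  ts3 <- project_series(ph$volume, pars, axis_offset = 3)
  expect_lt(abs(refine_tilt_axis(ts3) - 3), 0.5)
  expect_error(refine_tilt_axis(ts0, search_range = 0), "search_range")
})

test_that("reconstructing at the refined axis reduces artifacts and elongation", {
  ph <- fix_sphere(diameter = 20, voxel = 1, n = 64)
  ts3 <- project_series(ph$volume, fix_params(jitter_max = 0), axis_offset = 3)
  off <- refine_tilt_axis(ts3)
  good <- sirt(ts3, n_iter = 8, axis_offset = off)
  bad <- sirt(ts3, n_iter = 8, axis_offset = off + 3)
  worse <- sirt(ts3, n_iter = 8, axis_offset = off + 6)
  expect_gt(reconstruction_quality(good, ph$volume)$pearson_r,
            reconstruction_quality(bad, ph$volume)$pearson_r)
  # a badly mis-placed axis smears the sphere into an elongated arc
  expect_lt(nanovssa:::half_max_elongation(good),
            nanovssa:::half_max_elongation(worse))
})
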