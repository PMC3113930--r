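# Phantom generation: closed-form and oracle ground truths, seeded
# reproducibility, connectivity, and field placement.

test_that("sphere phantom carries closed-form truth and matching voxel volume", {
  ph <- fix_sphere(diameter = 20, voxel = 0.5, n = 56)
  expect_equal(ph$truth$area, 4 * pi * 100, tolerance = 1e-12)
  expect_equal(ph$truth$volume, 4 / 3 * pi * 1000, tolerance = 1e-12)
  expect_equal(ph$truth$vssa, 300, tolerance = 1e-12)
  expect_equal(ph$truth$provenance, "analytic")
  # anti-aliased voxel-count volume within 2% of the closed form
  vox_vol <- sum(ph$volume$values) * 0.5^3
  expect_lt(abs(vox_vol / ph$truth$volume - 1), 0.02)
})

test_that("sphere phantom rejects bad geometry", {
  sp <- particle_spec("sphere", diameter = 60)
  expect_error(make_sphere_phantom(sp, 1, c(48, 48, 48)), "exceeds")
  expect_error(make_sphere_phantom(particle_spec("sphere"), -1, c(48, 48, 48)),
               "voxel_size")
  expect_error(particle_spec("sphere", diameter = 0), "diameter")
})

test_that("voxel-count volume error shrinks as the voxel size halves", {
  err <- vapply(c(1, 0.5), function(h) {
    ph <- fix_sphere(diameter = 20, voxel = h, n = round(28 / h))
    mask <- volume3d(array(as.numeric(ph$volume$values >= 0.5),
                           dim(ph$volume$values)), h)
    abs(voxel_volume_oracle(mask) / ph$truth$volume - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("branched phantom degenerates to the sphere and spikes raise VSSA", {
  sp0 <- particle_spec("branched", diameter = 24, n_spikes = 0)
  br0 <- make_branched_phantom(sp0, 1, c(40, 40, 40))
  sph <- make_sphere_phantom(particle_spec("sphere", diameter = 24), 1,
                             c(40, 40, 40))
  expect_identical(br0$volume$values, sph$volume$values)
  # core 30 nm + 12 spikes: truth VSSA strictly above the bare core's 200
  spec <- particle_spec("branched", diameter = 30, n_spikes = 12,
                        spike_length = 10, spike_radius = 3, seed = 7)
  br <- make_branched_phantom(spec, 1, c(72, 72, 72))
  expect_equal(br$truth$provenance, "oracle")
  expect_gt(br$truth$vssa, 200)
  expect_error(make_branched_phantom(
    particle_spec("branched", diameter = 30, spike_length = -1), 1,
    c(72, 72, 72)), "spike")
})

test_that("seeded phantom generation is bit-reproducible", {
  spec <- particle_spec("branched", diameter = 30, n_spikes = 12, seed = 7)
  a <- make_branched_phantom(spec, 1, c(72, 72, 72))
  b <- make_branched_phantom(spec, 1, c(72, 72, 72))
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$area, b$truth$area)
  agg <- particle_spec("aggregate", n_subunits = 8, seed = 3)
  x <- make_aggregate_phantom(agg, 1, c(64, 64, 64))
  y <- make_aggregate_phantom(agg, 1, c(64, 64, 64))
  expect_identical(x$volume$values, y$volume$values)
})

test_that("aggregates form one connected component with VSSA below a lone sphere's", {
  spec <- particle_spec("aggregate", n_subunits = 15,
                        subunit_diameter_range = c(20, 20), seed = 3)
  agg <- make_aggregate_phantom(spec, 1, c(96, 96, 96))
  lab <- label_components(agg$volume, 0.5, min_voxels = 1)
  expect_equal(n_labels(lab), 1L)
  # neck merging removes surface relative to 15 isolated 20 nm spheres
  expect_lt(agg$truth$vssa, 300)
  expect_gt(agg$truth$vssa, 0)
  one <- make_aggregate_phantom(particle_spec("aggregate", n_subunits = 1,
                                              subunit_diameter_range = c(20, 20),
                                              seed = 1), 1, c(48, 48, 48))
  expect_lt(abs(one$truth$vssa / 300 - 1), 0.03)  # single subunit ~ sphere
})

test_that("rasterize_field places all particles and keeps per-particle truths", {
  specs <- lapply(1:11, function(i) particle_spec("sphere", diameter = 20,
                                                  seed = i))
  field <- rasterize_field(specs, 1, c(96, 96, 96), 5, seed = 1)
  lab <- label_components(field$volume, 0.5, min_voxels = 1)
  expect_equal(n_labels(lab), 11L)
  tot <- reference_metrics(field$truths)
  expect_equal(tot$volume, 11 * 4 / 3 * pi * 1000, tolerance = 1e-9)
  # single particle: identical to the direct phantom call
  f1 <- rasterize_field(specs[1], 1, c(48, 48, 48), 5, seed = 2)
  expect_equal(f1$truths[[1]]$area, specs[[1]]$diameter^2 * pi)
  # determinism
  f2 <- rasterize_field(specs, 1, c(96, 96, 96), 5, seed = 1)
  expect_identical(field$volume$values, f2$volume$values)
})

test_that("reference_metrics aggregates by totals", {
  t20 <- ground_truth(4 * pi * 100, 4 / 3 * pi * 1000)
  t10 <- ground_truth(4 * pi * 25, 4 / 3 * pi * 125)
  two <- reference_metrics(list(t20, t20))
  expect_equal(two$volume, 8377.58, tolerance = 1e-5)
  expect_equal(two$vssa, 300, tolerance = 1e-12)
  one <- reference_metrics(list(t20))
  expect_equal(one$area, t20$area)
  mixed <- reference_metrics(list(t10, t20))
  expect_gt(mixed$vssa, 300)
  expect_lt(mixed$vssa, 600)
  expect_error(reference_metrics(list()), "non-empty")
})
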