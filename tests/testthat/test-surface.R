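# Isosurface extraction and mesh metrology: closed-form solids, watertight
# topology, voxel-count cross-checks, VSSA arithmetic, and the
# resolution-loss property.

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- c("x", "y", "z")
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
             c(5, 6, 7), c(6, 8, 7),   # z = 1 face (+z)
             c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
             c(3, 7, 4), c(4, 7, 8),   # y = 1 (+y)
             c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
             c(2, 4, 6), c(4, 8, 6))   # x = 1 (+x)
  structure(list(vertices = v, faces = f, label = 0L), class = "surface_mesh")
}

test_that("mesh area and volume are exact on closed-form solids", {
  cube <- unit_cube_mesh()
  expect_true(is_watertight(cube))
  expect_equal(mesh_area(cube), 6.0, tolerance = 1e-12)
  expect_equal(mesh_volume(cube), 1.0, tolerance = 1e-12)
  tri <- structure(list(vertices = cbind(x = c(0, 3, 0), y = c(0, 0, 4),
                                         z = c(0, 0, 0)),
                        faces = matrix(c(1, 2, 3), 1), label = 0L),
                   class = "surface_mesh")
  expect_equal(mesh_area(tri), 6.0, tolerance = 1e-12)
  # translation invariance of the enclosed volume
  moved <- cube
  moved$vertices <- sweep(moved$vertices, 2, -c(100, -50, 3))
  expect_lt(abs(mesh_volume(moved) - 1), 1e-9)
  # open surfaces are rejected with the open-edge count
  open <- cube
  open$faces <- open$faces[-1, ]
  expect_error(mesh_volume(open), "not watertight")
})

test_that("voxelized ball meshes are watertight with spherical topology and 5% area accuracy", {
  ph <- fix_sphere(diameter = 20, voxel = 1, n = 32)
  m <- isosurface(ph$volume, 0.5)
  expect_true(is_watertight(m))
  nV <- nrow(m$vertices)
  nF <- nrow(m$faces)
  nE <- nF * 3 / 2                      # every edge shared by two faces
  expect_equal(nV - nE + nF, 2)         # Euler characteristic of a sphere
  expect_lt(abs(mesh_area(m) / (4 * pi * 100) - 1), 0.05)
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 1000) - 1), 0.05)
})

# icosphere oracle: subdivided icosahedron with vertices projected onto the
# sphere -- an analytic mesh independent of any voxel grid
icosphere <- function(r = 10, levels = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(levels)) {
    nf <- nrow(f)
    newf <- matrix(0L, nf * 4, 3)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      mids <- rbind((v[a, ] + v[b, ]) / 2, (v[b, ] + v[c3, ]) / 2,
                    (v[c3, ] + v[a, ]) / 2)
      idx <- nrow(v) + 1:3
      v <- rbind(v, mids)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, idx[1], idx[3]),
                                         c(b, idx[2], idx[1]),
                                         c(c3, idx[3], idx[2]),
                                         c(idx[1], idx[2], idx[3]))
    }
    f <- newf
    # merge duplicated midpoint vertices
    key <- paste(round(v[, 1], 9), round(v[, 2], 9), round(v[, 3], 9))
    uid <- match(key, key)
    vr <- sort(unique(uid))
    v <- v[vr, , drop = FALSE]
    f <- matrix(match(uid, vr)[f], ncol = 3)
  }
  v <- v * r / sqrt(rowSums(v^2))
  colnames(v) <- c("x", "y", "z")
  structure(list(vertices = v, faces = f, label = 0L), class = "surface_mesh")
}

test_that("refined icosphere metrology converges to the closed forms", {
  ico <- icosphere(r = 10, levels = 4)
  expect_true(is_watertight(ico))
  expect_lt(abs(mesh_area(ico) / (4 * pi * 100) - 1), 0.005)
  expect_lt(abs(mesh_volume(ico) / (4 / 3 * pi * 1000) - 1), 0.005)
})

test_that("anti-aliased rasterization measures closer than hard binary", {
  coarse <- fix_sphere(diameter = 20, voxel = 1, n = 32)
  hard <- coarse$volume
  hard$values <- array(as.numeric(hard$values >= 0.5), dim(hard$values))
  err_aa <- abs(mesh_area(isosurface(coarse$volume, 0.5)) / (4 * pi * 100) - 1)
  err_hard <- abs(mesh_area(isosurface(hard, 0.5)) / (4 * pi * 100) - 1)
  expect_lt(err_aa, err_hard)
})

test_that("mesh volume agrees with the voxel-count oracle on all phantom classes", {
  cases <- list(
    fix_sphere(diameter = 20, voxel = 1, n = 32),
    make_branched_phantom(particle_spec("branched", diameter = 30,
                                        n_spikes = 8, spike_length = 8,
                                        spike_radius = 4, seed = 2),
                          1, c(60, 60, 60)),
    make_aggregate_phantom(particle_spec("aggregate", n_subunits = 6,
                                         subunit_diameter_range = c(16, 20),
                                         seed = 4), 1, c(80, 80, 80)))
  for (ph in cases) {
    m <- isosurface(ph$volume, 0.5)
    mask <- volume3d(array(as.numeric(ph$volume$values >= 0.5),
                           dim(ph$volume$values)), ph$volume$voxel_size)
    expect_lt(abs(mesh_volume(m) / voxel_volume_oracle(mask) - 1), 0.05)
    # isoperimetric inequality for every measured particle
    expect_gte(mesh_area(m), (36 * pi * mesh_volume(m)^2)^(1 / 3))
  }
})

test_that("voxel_volume_oracle counts and guards", {
  v <- array(0, c(9, 9, 9))
  v[3:7, 3:7, 3:7] <- 1
  expect_equal(voxel_volume_oracle(volume3d(v, 1)), 125)
  ph <- fix_sphere(diameter = 20, voxel = 1, n = 32)
  mask <- volume3d(array(as.numeric(ph$volume$values >= 0.5),
                         dim(ph$volume$values)), 1)
  expect_lt(abs(voxel_volume_oracle(mask) / (4 / 3 * pi * 1000) - 1), 0.02)
  expect_error(voxel_volume_oracle(volume3d(array(0, c(4, 4, 4)), 1)), "empty")
  expect_error(voxel_volume_oracle(volume3d(array(0.5, c(4, 4, 4)), 1)),
               "binary")
})

test_that("compute_vssa applies the exact unit identity and classification", {
  perfect <- compute_vssa(4 * pi * 100, 4 / 3 * pi * 1000)
  expect_equal(perfect$vssa, 300, tolerance = 1e-12)
  expect_true(perfect$nanostructured)
  # published worked example: the area/volume ratio gives 358.5, not the
  # printed 332
  worked <- compute_vssa(13895, 38763)
  expect_equal(worked$vssa, 358.5, tolerance = 0.05)
  expect_equal(compute_vssa(13895 / 2, 38763)$vssa, worked$vssa / 2,
               tolerance = 1e-12)
  expect_false(compute_vssa(59.9, 1000)$nanostructured)
  expect_error(compute_vssa(100, 0), "volume")
  expect_error(compute_vssa(0, 100), "area")
})

test_that("measured sphere VSSA converges toward 6/d with resolution", {
  errs <- vapply(c(1, 0.5), function(h) {
    ph <- fix_sphere(diameter = 20, voxel = h, n = round(32 / h))
    m <- isosurface(ph$volume, 0.5)
    abs(compute_vssa(mesh_area(m), mesh_volume(m))$vssa - 300)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("progressive blurring never increases the measured VSSA of a branched particle", {
  ph <- make_branched_phantom(particle_spec("branched", diameter = 30,
                                            n_spikes = 12, spike_length = 10,
                                            spike_radius = 3, seed = 7),
                              1, c(72, 72, 72))
  vssa_at <- vapply(c(0, 1, 2, 3), function(s) {
    v <- if (s > 0) gaussian_blur3d(ph$volume, s) else ph$volume
    m <- isosurface(v, 0.5)
    compute_vssa(mesh_area(m), mesh_volume(m))$vssa
  }, numeric(1))
  expect_true(all(diff(vssa_at) <= 1e-6))
})

test_that("isosurface guards empty, full and boundary-touching foregrounds", {
  ph <- fix_sphere(diameter = 20, voxel = 1, n = 32)
  expect_error(isosurface(ph$volume, 2), "empty or full")
  touching <- array(0, c(16, 16, 16))
  touching[1:9, 5:12, 5:12] <- 1           # slab reaching the z = 0 face
  expect_error(isosurface(volume3d(touching, 1), 0.5), "boundary")
})

test_that("per-particle metrics are measured on separated closed surfaces", {
  specs <- lapply(1:3, function(i) particle_spec("sphere", diameter = 16,
                                                 seed = i))
  field <- rasterize_field(specs, 1, rep(56, 3), 5, seed = 8)
  lab <- label_components(field$volume, 0.5)
  met <- mesh_metrics(field$volume, lab, 0.5)
  expect_equal(nrow(met), 3)
  expect_true(all(met$watertight))
  expect_lt(max(abs(met$vssa_m2cm3 - 375)) / 375, 0.1)  # 6/16 nm^-1
})
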