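# Voxel phantoms of the three specimen classes used throughout:
# ~20 nm spherical gold, ~50 nm branched gold (core + surface extensions),
# and silica-like aggregates of interconnected 8-20 nm spherical subunits.
# All geometry is built from signed-distance primitives (spheres, capsules)
# and rasterized with 3x3x3 subvoxel anti-aliasing at the boundary.

#' Particle specification
#'
#' Describes one particle to be rasterized as a phantom.  `diameter` is the
#' sphere diameter for `kind = "sphere"`, the core diameter for
#' `"branched"`, and ignored for `"aggregate"` (subunit diameters are drawn
#' from `subunit_diameter_range`).  For branched particles `spike_length` is
#' the protrusion of each spike beyond the core surface, rounded tip
#' included, so the overall particle diameter is
#' `diameter + 2 * spike_length`.
#'
#' @param kind `"sphere"`, `"branched"` or `"aggregate"`.
#' @param center 3-vector (nm) `(z, y, x)`, or `NULL` to let
#'   [rasterize_field()] place the particle.
#' @param diameter core/sphere diameter in nm (> 0).
#' @param n_spikes number of surface extensions (branched only, >= 0).
#' @param spike_length,spike_radius spike geometry in nm (branched only).
#' @param n_subunits number of spherical subunits (aggregate only, >= 1).
#' @param subunit_diameter_range length-2 numeric (nm), low <= high.
#' @param seed integer seed making all generated geometry reproducible.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(kind = c("sphere", "branched", "aggregate"),
                          center = NULL, diameter = 20,
                          n_spikes = 12L, spike_length = 10, spike_radius = 3,
                          n_subunits = 10L,
                          subunit_diameter_range = c(8, 20),
                          seed = 1L) {
  kind <- match.arg(kind)
  if (diameter <= 0) stop("`diameter` must be > 0")
  if (n_spikes < 0) stop("`n_spikes` must be >= 0")
  if (n_subunits < 1) stop("`n_subunits` must be >= 1")
  if (length(subunit_diameter_range) != 2 ||
      subunit_diameter_range[1] > subunit_diameter_range[2])
    stop("`subunit_diameter_range` must be c(low, high) with low <= high")
  structure(list(kind = kind, center = center, diameter = diameter,
                 n_spikes = as.integer(n_spikes), spike_length = spike_length,
                 spike_radius = spike_radius, n_subunits = as.integer(n_subunits),
                 subunit_diameter_range = as.numeric(subunit_diameter_range),
                 seed = as.integer(seed)),
            class = "particle_spec")
}

#' Ground-truth record for a phantom particle
#'
#' Reference surface area and volume, either in closed form (spheres) or
#' measured on a 4x-finer rasterization of the same implicit geometry by the
#' isosurface metrology code (`provenance = "oracle"`).
#'
#' @param area,volume reference area (nm^2) and volume (nm^3), > 0.
#' @param provenance `"analytic"` or `"oracle"`.
#' @return An object of class `ground_truth` with fields `area`, `volume`,
#'   `vssa` (m^2/cm^3) and `provenance`; `true_shifts` is filled by
#'   [apply_jitter()].
#' @export
ground_truth <- function(area, volume, provenance = c("analytic", "oracle")) {
  provenance <- match.arg(provenance)
  stopifnot(area > 0, volume > 0)
  structure(list(area = area, volume = volume,
                 vssa = area / volume * NM_INV_TO_M2_CM3,
                 provenance = provenance, true_shifts = NULL),
            class = "ground_truth")
}

# ---- signed-distance primitives -----------------------------------------

sphere_prim <- function(center, r) list(type = "sphere", center = center, r = r)
capsule_prim <- function(a, b, r) list(type = "capsule", a = a, b = b, r = r)

# signed distance of points (n x 3 matrix, nm, columns z,y,x) to a primitive
prim_sdf <- function(prim, pts) {
  if (prim$type == "sphere") {
    d <- sqrt((pts[, 1] - prim$center[1])^2 +
              (pts[, 2] - prim$center[2])^2 +
              (pts[, 3] - prim$center[3])^2)
    d - prim$r
  } else {
    ab <- prim$b - prim$a
    len2 <- sum(ab^2)
    if (len2 == 0) return(prim_sdf(sphere_prim(prim$a, prim$r), pts))
    t <- ((pts[, 1] - prim$a[1]) * ab[1] + (pts[, 2] - prim$a[2]) * ab[2] +
          (pts[, 3] - prim$a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((pts[, 1] - (prim$a[1] + t * ab[1]))^2 +
              (pts[, 2] - (prim$a[2] + t * ab[2]))^2 +
              (pts[, 3] - (prim$a[3] + t * ab[3]))^2)
    d - prim$r
  }
}

prims_sdf <- function(prims, pts) {
  d <- prim_sdf(prims[[1]], pts)
  for (p in prims[-1]) d <- pmin(d, prim_sdf(p, pts))
  d
}

# overall bounding radius of a primitive set about a reference point
prims_extent <- function(prims, center) {
  mx <- 0
  for (p in prims) {
    if (p$type == "sphere") {
      mx <- max(mx, sqrt(sum((p$center - center)^2)) + p$r)
    } else {
      mx <- max(mx, sqrt(sum((p$a - center)^2)) + p$r,
                sqrt(sum((p$b - center)^2)) + p$r)
    }
  }
  mx
}

# ---- rasterization -------------------------------------------------------

# Rasterize a primitive union into an existing density array (modified in
# place via return).  Interior voxels get density 1; boundary voxels (within
# half a voxel diagonal of the surface) get the fraction of a 3x3x3 subvoxel
# grid falling inside.
rasterize_prims <- function(prims, values, voxel_size, origin) {
  d <- dim(values)
  ext_lo <- rep(Inf, 3); ext_hi <- rep(-Inf, 3)
  for (p in prims) {
    cs <- if (p$type == "sphere") list(p$center) else list(p$a, p$b)
    for (cc in cs) {
      ext_lo <- pmin(ext_lo, cc - p$r)
      ext_hi <- pmax(ext_hi, cc + p$r)
    }
  }
  h <- voxel_size
  band <- h * sqrt(3) / 2
  idx_lo <- pmax(1L, floor((ext_lo - band - origin) / h + 0.5))
  idx_hi <- pmin(d, ceiling((ext_hi + band - origin) / h + 0.5))
  if (any(idx_lo > idx_hi)) return(values)
  iz <- idx_lo[1]:idx_hi[1]; iy <- idx_lo[2]:idx_hi[2]; ix <- idx_lo[3]:idx_hi[3]
  ctr <- as.matrix(expand.grid(z = origin[1] + (iz - 0.5) * h,
                               y = origin[2] + (iy - 0.5) * h,
                               x = origin[3] + (ix - 0.5) * h))
  sdf <- prims_sdf(prims, ctr)
  dens <- as.numeric(sdf <= -band)
  bnd <- which(abs(sdf) < band)
  if (length(bnd)) {
    offs <- as.matrix(expand.grid(z = c(-1, 0, 1) / 3 * h,
                                  y = c(-1, 0, 1) / 3 * h,
                                  x = c(-1, 0, 1) / 3 * h))
    frac <- numeric(length(bnd))
    for (k in seq_len(nrow(offs))) {
      sub <- sweep(ctr[bnd, , drop = FALSE], 2, -offs[k, ])
      frac <- frac + (prims_sdf(prims, sub) < 0)
    }
    dens[bnd] <- frac / nrow(offs)
  }
  dens <- array(dens, c(length(iz), length(iy), length(ix)))
  values[iz, iy, ix] <- pmax(values[iz, iy, ix], dens)
  values
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

runif_sphere_dirs <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(z, s * cos(phi), s * sin(phi))   # (z, y, x)
}

# build the primitive list for a spec (geometry only, centre required)
particle_prims <- function(spec) {
  ctr <- spec$center
  switch(spec$kind,
    sphere = list(sphere_prim(ctr, spec$diameter / 2)),
    branched = {
      r <- spec$diameter / 2
      prims <- list(sphere_prim(ctr, r))
      if (spec$n_spikes > 0) {
        if (spec$spike_length <= 0 || spec$spike_radius <= 0)
          stop("spike_length and spike_radius must be > 0")
        dirs <- with_seed(spec$seed, runif_sphere_dirs(spec$n_spikes))
        tip <- r + spec$spike_length - spec$spike_radius
        for (i in seq_len(spec$n_spikes))
          prims <- c(prims, list(capsule_prim(ctr, ctr + tip * dirs[i, ],
                                              spec$spike_radius)))
      }
      prims
    },
    aggregate = aggregate_prims(spec))
}

# random-walk growth: each new subunit is attached to a randomly chosen
# existing one at centre distance 0.8 * (r_i + r_new), guaranteeing overlap
# and hence a single connected component
aggregate_prims <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    rng <- spec$subunit_diameter_range / 2
    rs <- runif(spec$n_subunits, rng[1], rng[2])
    centers <- matrix(0, spec$n_subunits, 3)
    centers[1, ] <- spec$center
    if (spec$n_subunits > 1) {
      for (i in 2:spec$n_subunits) {
        j <- sample.int(i - 1, 1)
        dir <- runif_sphere_dirs(1)
        centers[i, ] <- centers[j, ] + 0.8 * (rs[j] + rs[i]) * dir
      }
    }
    lapply(seq_len(spec$n_subunits),
           function(i) sphere_prim(centers[i, ], rs[i]))
  })
}

check_fit <- function(prims, center, voxel_size, grid_shape, what) {
  ext <- prims_extent(prims, center)
  lo <- center - ext
  hi <- center + ext
  margin <- 2 * voxel_size
  if (any(lo < margin) || any(hi > grid_shape * voxel_size - margin))
    stop(sprintf("%s (extent %.1f nm about centre) exceeds the %s grid with a 2-voxel margin",
                 what, ext, paste(grid_shape, collapse = "x")))
}

default_center <- function(grid_shape, voxel_size)
  grid_shape * voxel_size / 2

# fine-grid isosurface oracle for non-analytic truths: rasterize the same
# implicit geometry at 4x-finer voxels over a tight bounding box and measure
# the half-density isosurface mesh
oracle_truth <- function(prims, voxel_size) {
  fine <- voxel_size / 4
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (p in prims) {
    cs <- if (p$type == "sphere") list(p$center) else list(p$a, p$b)
    for (cc in cs) { lo <- pmin(lo, cc - p$r); hi <- pmax(hi, cc + p$r) }
  }
  pad <- 4 * fine
  origin <- lo - pad
  shape <- ceiling((hi - lo + 2 * pad) / fine)
  vals <- array(0, shape)
  vals <- rasterize_prims(prims, vals, fine, origin)
  vol <- volume3d(vals, fine, origin)
  mesh <- isosurface(vol, 0.5)
  ground_truth(mesh_area(mesh), mesh_volume(mesh), provenance = "oracle")
}

# ---- exported phantom builders ------------------------------------------

#' Spherical nanoparticle phantom
#'
#' Rasterizes a single sphere (default 20 nm, the size of the colloidal gold
#' control particles) with partial-volume anti-aliasing; the ground truth
#' carries the closed forms `4*pi*r^2` and `4/3*pi*r^3`.
#'
#' @param spec a [particle_spec()] with `kind = "sphere"`.
#' @param voxel_size voxel edge in nm (> 0).
#' @param grid_shape integer 3-vector `(nz, ny, nx)`.
#' @return `list(volume = <volume3d>, truth = <ground_truth>)`.
#' @export
make_sphere_phantom <- function(spec, voxel_size, grid_shape) {
  stopifnot(inherits(spec, "particle_spec"))
  if (spec$kind != "sphere") stop("spec$kind must be 'sphere'")
  if (voxel_size <= 0) stop("`voxel_size` must be > 0")
  grid_shape <- as.integer(grid_shape)
  if (is.null(spec$center)) spec$center <- default_center(grid_shape, voxel_size)
  prims <- particle_prims(spec)
  check_fit(prims, spec$center, voxel_size, grid_shape, "sphere")
  vals <- rasterize_prims(prims, array(0, grid_shape), voxel_size, c(0, 0, 0))
  r <- spec$diameter / 2
  list(volume = volume3d(vals, voxel_size),
       truth = ground_truth(4 * pi * r^2, 4 / 3 * pi * r^3, "analytic"))
}

#' Branched nanoparticle phantom
#'
#' Union of a central sphere and `n_spikes` capsules (cylinders with
#' hemispherical caps) pointing in directions drawn uniformly on the sphere
#' from the particle's seed; emulates ~50 nm branched gold particles with
#' surface extensions.  With `n_spikes = 0` this degenerates to
#' [make_sphere_phantom()] (but with oracle ground truth).  Ground truth is
#' measured on a 4x-finer rasterization of the same geometry.
#'
#' @inheritParams make_sphere_phantom
#' @return `list(volume, truth)` as in [make_sphere_phantom()].
#' @export
make_branched_phantom <- function(spec, voxel_size, grid_shape) {
  stopifnot(inherits(spec, "particle_spec"))
  if (spec$kind != "branched") stop("spec$kind must be 'branched'")
  if (voxel_size <= 0) stop("`voxel_size` must be > 0")
  grid_shape <- as.integer(grid_shape)
  if (is.null(spec$center)) spec$center <- default_center(grid_shape, voxel_size)
  prims <- particle_prims(spec)
  check_fit(prims, spec$center, voxel_size, grid_shape, "branched particle")
  vals <- rasterize_prims(prims, array(0, grid_shape), voxel_size, c(0, 0, 0))
  list(volume = volume3d(vals, voxel_size), truth = oracle_truth(prims, voxel_size))
}

#' Aggregated nanomaterial phantom
#'
#' Random-walk aggregate of overlapping spherical subunits emulating the
#' NM-200/NM-203 silica morphology: each new subunit (diameter drawn
#' uniformly from `subunit_diameter_range`) attaches to a randomly chosen
#' existing subunit at a centre distance of 0.8 times the sum of radii, so
#' the result is always one connected component with visible necks.  If the
#' aggregate grows outside the grid the growth is re-seeded up to 10 times
#' before rejection.
#'
#' @inheritParams make_sphere_phantom
#' @return `list(volume, truth)`; truth provenance is `"oracle"`.
#' @export
make_aggregate_phantom <- function(spec, voxel_size, grid_shape) {
  stopifnot(inherits(spec, "particle_spec"))
  if (spec$kind != "aggregate") stop("spec$kind must be 'aggregate'")
  if (voxel_size <= 0) stop("`voxel_size` must be > 0")
  grid_shape <- as.integer(grid_shape)
  if (is.null(spec$center)) spec$center <- default_center(grid_shape, voxel_size)
  prims <- NULL
  for (attempt in 0:9) {
    cand <- aggregate_prims(spec, seed = spec$seed + attempt * 10000L)
    ok <- tryCatch({
      check_fit(cand, spec$center, voxel_size, grid_shape, "aggregate")
      TRUE
    }, error = function(e) FALSE)
    if (ok) { prims <- cand; break }
  }
  if (is.null(prims))
    stop("aggregate grows outside the grid; 10 reseeded attempts failed")
  vals <- rasterize_prims(prims, array(0, grid_shape), voxel_size, c(0, 0, 0))
  list(volume = volume3d(vals, voxel_size), truth = oracle_truth(prims, voxel_size))
}

#' Rasterize a field of particles into one volume
#'
#' Emulates a reconstruction containing several particles (the control data
#' held 1 to 11 gold particles per tomogram).  Specs without a centre are
#' placed from `seed` in one of two modes:
#'
#' * `"support"` (default): particles rest on the carbon support film, i.e.
#'   their centres sit one radius above a common plane near mid-height (with
#'   a 2 nm settle jitter) -- how grid-deposited specimens actually lie.
#'   Placement picks, per particle, the best of 200 random candidates by
#'   maximal minimum surface gap *in the (y, x) projection*, so particles
#'   stay apart in the zero-tilt image whenever the field of view allows.
#'   Dense fields (many large particles in a small grid) may still touch in
#'   projection; placement is rejected only when the best candidate would
#'   overlap by more than a quarter of the smaller radius.
#' * `"volume"`: uniform placement inside the rotation-safe cylinder with
#'   3D surface separation at least `min_separation` (up to 100 attempts per
#'   particle, then rejection).  This mode produces 3D-separated particles
#'   that can superimpose in projection.
#'
#' @param specs list of [particle_spec()].
#' @param voxel_size voxel edge (nm).
#' @param grid_shape integer 3-vector `(nz, ny, nx)`.
#' @param min_separation minimum surface-to-surface distance (nm).
#' @param seed placement seed.
#' @param placement `"support"` or `"volume"`.
#' @return `list(volume = <volume3d>, truths = list of <ground_truth>)` in
#'   placement order.
#' @export
rasterize_field <- function(specs, voxel_size, grid_shape, min_separation = 5,
                            seed = 1L, placement = c("support", "volume")) {
  if (length(specs) < 1) stop("need at least one particle spec")
  placement <- match.arg(placement)
  grid_shape <- as.integer(grid_shape)
  ext_of <- function(spec) {
    switch(spec$kind,
      sphere = spec$diameter / 2,
      branched = spec$diameter / 2 + spec$spike_length,
      aggregate = {
        p <- aggregate_prims(replace_center(spec, c(0, 0, 0)))
        prims_extent(p, c(0, 0, 0))
      })
  }
  exts <- vapply(specs, ext_of, numeric(1))
  L <- grid_shape * voxel_size
  ctr_zx <- c(L[1], L[3]) / 2
  margin <- 2 * voxel_size
  placed <- vector("list", length(specs))
  with_seed(seed, {
    order_i <- order(-exts)  # large particles first: easier packing
    for (i in if (placement == "support") order_i else seq_along(specs)) {
      sp <- specs[[i]]
      if (!is.null(sp$center)) {
        placed[[i]] <- sp$center
        next
      }
      rmax <- min(L[1], L[3]) / 2 - exts[i] - margin
      if (rmax <= 0)
        stop(sprintf("particle %d (extent %.1f nm) cannot fit the rotation-safe region", i, exts[i]))
      prev <- which(!vapply(placed, is.null, logical(1)))
      if (placement == "support") {
        z_support <- L[1] / 2 - max(exts)  # film plane; centres at z + r
        best <- NULL
        best_gap <- -Inf
        for (attempt in seq_len(400)) {
          xx <- runif(1, ctr_zx[2] - rmax, ctr_zx[2] + rmax)
          yy <- runif(1, exts[i] + margin, L[2] - exts[i] - margin)
          zz <- z_support + exts[i] + runif(1, -2, 2)
          gap <- Inf
          for (j in prev) {
            g <- sqrt((yy - placed[[j]][2])^2 + (xx - placed[[j]][3])^2) -
              exts[i] - exts[j]
            gap <- min(gap, g)
          }
          if (gap < min_separation) {
            # crowded field: settle the particle on top of its projected
            # neighbours (second layer) so the 3D surface separation still
            # meets min_separation where projections superimpose.  A sphere
            # cannot rest centred on another's apex (unstable equilibrium):
            # it rolls into a pocket between neighbours -- centre distance
            # ~0.87 of the summed radii for equal touching supports -- so
            # candidates sitting more squarely on top are rejected.
            pocket_ok <- TRUE
            for (j in prev) {
              pd <- sqrt((yy - placed[[j]][2])^2 + (xx - placed[[j]][3])^2)
              req <- exts[i] + exts[j] + min_separation
              if (pd < req) {
                if (pd < 0.85 * (exts[i] + exts[j])) pocket_ok <- FALSE
                zz <- max(zz, placed[[j]][1] + sqrt(req^2 - pd^2))
              }
            }
            if (!pocket_ok && attempt < 380) next
          }
          if (sqrt((zz - ctr_zx[1])^2 + (xx - ctr_zx[2])^2) > rmax) next
          if (gap > best_gap) { best_gap <- gap; best <- c(zz, yy, xx) }
          if (best_gap >= min_separation) break
        }
        if (is.null(best))
          stop(sprintf("could not place particle %d (kind %s, extent %.1f nm) in the rotation-safe region",
                       i, sp$kind, exts[i]))
        placed[[i]] <- best
      } else {
        ok <- FALSE
        for (attempt in seq_len(100)) {
          rho <- sqrt(runif(1)) * rmax
          th <- runif(1, 0, 2 * pi)
          yy <- runif(1, exts[i] + margin, L[2] - exts[i] - margin)
          cand <- c(ctr_zx[1] + rho * cos(th), yy, ctr_zx[2] + rho * sin(th))
          clear <- TRUE
          for (j in prev) {
            gap <- sqrt(sum((cand - placed[[j]])^2)) - exts[i] - exts[j]
            if (gap < min_separation) { clear <- FALSE; break }
          }
          if (clear) { placed[[i]] <- cand; ok <- TRUE; break }
        }
        if (!ok)
          stop(sprintf("could not place particle %d (kind %s, extent %.1f nm) within 100 attempts",
                       i, sp$kind, exts[i]))
      }
    }
  })
  vals <- array(0, grid_shape)
  truths <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- replace_center(specs[[i]], placed[[i]])
    out <- switch(sp$kind,
      sphere = make_sphere_phantom(sp, voxel_size, grid_shape),
      branched = make_branched_phantom(sp, voxel_size, grid_shape),
      aggregate = make_aggregate_phantom(sp, voxel_size, grid_shape))
    vals <- pmax(vals, out$volume$values)
    truths[[i]] <- out$truth
  }
  dim(vals) <- grid_shape
  list(volume = volume3d(vals, voxel_size), truths = truths)
}

replace_center <- function(spec, center) { spec$center <- center; spec }

#' Aggregate reference metrics over a list of ground truths
#'
#' Totals are sums; the aggregate VSSA is total area over total volume (not
#' the mean of per-particle VSSAs), matching how total surface area and
#' volume are measured per reconstruction.
#'
#' @param truths non-empty list of [ground_truth()] objects.
#' @return `list(area, volume, vssa)` in nm^2, nm^3, m^2/cm^3.
#' @export
reference_metrics <- function(truths) {
  if (length(truths) == 0) stop("`truths` must be non-empty")
  area <- sum(vapply(truths, `[[`, numeric(1), "area"))
  volume <- sum(vapply(truths, `[[`, numeric(1), "volume"))
  list(area = area, volume = volume,
       vssa = area / volume * NM_INV_TO_M2_CM3)
}
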