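# Isosurface extraction and watertight-mesh metrology: triangulated surface,
# area, divergence-theorem volume, and the VSSA in m^2/cm^3.
#
# Isosurfaces are extracted by marching tetrahedra on the Freudenthal 6-tet
# decomposition of the voxel lattice.  Unlike classic marching cubes this has
# no ambiguous cases, so the mesh is watertight and consistently oriented by
# construction -- the property the enclosed-volume integral depends on.

#' Extract a triangulated isosurface
#'
#' Runs marching tetrahedra at the given iso-level.  Vertex coordinates are
#' in nm (`origin + (index + 1/2) * voxel_size`), columns `(x, y, z)`;
#' triangles are consistently oriented with outward normals (foreground to
#' background).  When a [label_components()] result and a label are given,
#' the volume is restricted to that particle's bounding box padded by `pad`
#' voxels, and voxels above the threshold that belong to other labels are
#' suppressed so each particle yields its own closed surface.
#'
#' Before marching, the field is regularized with a sub-voxel Gaussian
#' (`presmooth` standard deviation, in voxels).  Voxel-sharp boundaries
#' otherwise inflate the triangulated area by several percent through
#' lattice-scale bumpiness; a 0.5-voxel regularization removes that bias
#' while moving the iso-contour by well under half a voxel.  The residual
#' curvature bias grows for very small particles; metrology is accurate for
#' feature radii of about 8 voxels and up.  Set `presmooth = 0` for raw
#' marching.
#'
#' @param vol a [volume3d].
#' @param threshold iso-level, within the volume's value range.
#' @param labels optional `label_volume` matching `vol`.
#' @param label particle label to mesh (required with `labels`).
#' @param pad bounding-box padding in voxels (default 2).
#' @param presmooth Gaussian regularization sigma in voxels (default 0.5).
#' @return An object of class `surface_mesh` with `vertices` (n x 3 nm),
#'   `faces` (m x 3 vertex indices) and `label`.
#' @export
isosurface <- function(vol, threshold, labels = NULL, label = NULL, pad = 2,
                       presmooth = 0.5) {
  stopifnot(is_volume3d(vol))
  v <- vol$values
  origin <- vol$origin
  lab_out <- 0L
  if (!is.null(labels)) {
    if (is.null(label)) stop("`label` is required when `labels` is given")
    stopifnot(inherits(labels, "label_volume"),
              identical(dim(labels$values), dim(v)))
    idx <- which(labels$values == label, arr.ind = TRUE)
    if (nrow(idx) == 0) stop(sprintf("label %d not present", label))
    d <- dim(v)
    lo <- pmax(apply(idx, 2, min) - pad, 1)
    hi <- pmin(apply(idx, 2, max) + pad, d)
    lv <- labels$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    v <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    bg <- min(v)
    # suppress other particles' cores, then keep only the part of the
    # iso-level foreground connected to this particle; this allows meshing
    # at an iso below the labelling threshold (the particle's shell stays)
    # without picking up neighbours or stray debris
    v[lv > 0L & lv != label] <- bg
    mask <- array(as.integer(v >= threshold), dim(v))
    cc <- cpp_label_components(mask, dim(v), 26L)
    own <- unique(cc[lv == label])
    own <- own[own > 0L]
    if (length(own) == 0) stop(sprintf("label %d has no voxels at this iso-level", label))
    v[mask == 1L & !(cc %in% own)] <- bg
    origin <- origin + (lo - 1) * vol$voxel_size
    lab_out <- as.integer(label)
  }
  if (all(v >= threshold) || all(v < threshold))
    stop("empty or full foreground at this iso-level")
  d <- dim(v)
  boundary_fg <- any(v[c(1, d[1]), , ] >= threshold) ||
    any(v[, c(1, d[2]), ] >= threshold) ||
    any(v[, , c(1, d[3])] >= threshold)
  if (boundary_fg)
    stop("foreground touches the volume boundary; the surface would not close (use exclude_border or pad the volume)")
  if (presmooth > 0) {
    # blur relative to the background level so offset backgrounds stay put
    bg_lvl <- min(v)
    sm <- gaussian_blur3d(volume3d(v - bg_lvl, 1), presmooth)
    v <- sm$values + bg_lvl
  }
  tris <- cpp_marching_tets(v, d, threshold)
  if (nrow(tris) == 0) stop("empty isosurface")
  h <- vol$voxel_size
  # tris columns: v0(z,y,x), v1(z,y,x), v2(z,y,x) in 0-based index coords.
  # Convert to world nm with columns (x, y, z); the axis permutation
  # (z,y,x)->(x,y,z) mirrors orientation, so swap v1/v2 to keep outward
  # normals.
  conv <- function(m) cbind(origin[3] + (m[, 3] + 0.5) * h,
                            origin[2] + (m[, 2] + 0.5) * h,
                            origin[1] + (m[, 1] + 0.5) * h)
  pts <- rbind(conv(tris[, 1:3, drop = FALSE]),
               conv(tris[, 7:9, drop = FALSE]),
               conv(tris[, 4:6, drop = FALSE]))
  n <- nrow(tris)
  key <- paste(round(pts[, 1] / h * 1e6), round(pts[, 2] / h * 1e6),
               round(pts[, 3] / h * 1e6))
  uid <- match(key, key)
  vert_rows <- sort(unique(uid))
  vid <- match(uid, vert_rows)
  vertices <- pts[vert_rows, , drop = FALSE]
  colnames(vertices) <- c("x", "y", "z")
  faces <- cbind(vid[seq_len(n)], vid[n + seq_len(n)], vid[2 * n + seq_len(n)])
  # drop degenerate faces (duplicate vertices after merging)
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  faces <- faces[!degen, , drop = FALSE]
  mesh <- structure(list(vertices = vertices, faces = faces, label = lab_out),
                    class = "surface_mesh")
  if (!is_watertight(mesh))
    warning("isosurface mesh is not watertight; enclosed volume will be rejected")
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) ", watertight" else ", NOT watertight"))
  invisible(x)
}

edge_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Is a mesh watertight?
#'
#' A closed edge-manifold surface has every undirected edge shared by
#' exactly two faces.
#'
#' @param mesh a `surface_mesh`.
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(edge_counts(mesh) == 2)
}

#' Surface area of a mesh
#'
#' Sum of triangle areas (half cross-product magnitudes).
#'
#' @param mesh a `surface_mesh` with at least one face.
#' @return Area in nm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0) stop("mesh has no faces")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem sum of signed tetrahedra spanned by each face and the
#' origin; translation-invariant, absolute value returned.  Rejects
#' non-watertight meshes (reporting the number of open edges).
#'
#' @param mesh a watertight, consistently oriented `surface_mesh`.
#' @return Volume in nm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0) stop("mesh has no faces")
  ec <- edge_counts(mesh)
  if (!all(ec == 2))
    stop(sprintf("mesh is not watertight: %d edge(s) not shared by exactly 2 faces",
                 sum(ec != 2)))
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  v1 <- v[f[, 2], , drop = FALSE]
  v2 <- v[f[, 3], , drop = FALSE]
  det <- v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
         v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
         v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  abs(sum(det)) / 6
}

#' Voxel-counting volume oracle
#'
#' Independent volume estimate for a binary mask: foreground voxel count
#' times the voxel volume.  Used to cross-check [mesh_volume()].
#'
#' @param mask a [volume3d] whose values are 0/1 (or logical).
#' @return Volume in nm^3.
#' @export
voxel_volume_oracle <- function(mask) {
  stopifnot(is_volume3d(mask))
  v <- mask$values
  if (!all(v %in% c(0, 1))) stop("`mask` must be binary")
  n <- sum(v)
  if (n == 0) stop("empty mask")
  n * mask$voxel_size^3
}

#' Volume-specific surface area
#'
#' `VSSA = area / volume * 1000` converts an nm^2/nm^3 ratio to m^2/cm^3
#' (unit identity: 1 nm^-1 = 1000 m^2/cm^3).  A material with VSSA above
#' 60 m^2/cm^3 is classified as nanostructured under the European
#' Commission's proposed definition.
#'
#' Note on the published worked example: a particle set with total area
#' 13,895 nm^2 and volume 38,763 nm^3 has VSSA
#' `13895 / 38763 * 1000 = 358.5` m^2/cm^3; the originally reported value of
#' 332 m^2/cm^3 for these inputs is arithmetically inconsistent with the
#' ratio (possibly smoothed-surface or rounding differences) and is not
#' reproduced here.
#'
#' @param area surface area in nm^2 (> 0).
#' @param volume enclosed volume in nm^3 (> 0).
#' @return `list(vssa, nanostructured)` with VSSA in m^2/cm^3 and the
#'   classification against the 60 m^2/cm^3 threshold.
#' @export
compute_vssa <- function(area, volume) {
  if (!is.numeric(volume) || volume <= 0) stop("`volume` must be > 0")
  if (!is.numeric(area) || area <= 0) stop("`area` must be > 0")
  vssa <- area / volume * NM_INV_TO_M2_CM3
  list(vssa = vssa, nanostructured = vssa > VSSA_THRESHOLD)
}

#' EC nanostructure VSSA threshold (m^2/cm^3)
#' @export
VSSA_THRESHOLD <- 60

#' Per-particle isosurface metrology
#'
#' Meshes every labelled particle on its padded bounding box and measures
#' area, enclosed volume and VSSA.
#'
#' With `local_iso = TRUE`, each particle is meshed at its own iso-level:
#' halfway between the volume's background mode and the particle's interior
#' density (the 90th percentile of its labelled voxels).  The half-interior
#' contour of a blurred density step marks the true boundary, so this
#' per-particle choice -- the metrology analogue of matching the surface to
#' each specimen's orthoslice boundaries -- is insensitive to the
#' reconstruction-amplitude variations that a single global level inherits.
#' With `local_iso = FALSE` every particle is meshed at `threshold`.
#'
#' @param vol the grey [volume3d] the labels were derived from.
#' @param labels a [label_components()] result.
#' @param threshold the iso-level used for segmentation.
#' @param pad bounding-box padding in voxels.
#' @param presmooth passed to [isosurface()].
#' @param local_iso mesh each particle at half its own interior density
#'   (default `TRUE`).
#' @return A data frame with columns `label`, `iso_level`, `area_nm2`,
#'   `volume_nm3`, `vssa_m2cm3`, `watertight`.
#' @export
mesh_metrics <- function(vol, labels, threshold, pad = 2, presmooth = 0.5,
                         local_iso = TRUE) {
  stopifnot(inherits(labels, "label_volume"))
  k <- n_labels(labels)
  bg <- if (local_iso) {
    h <- grey_histogram(vol)
    bin_centres(h)[which.max(movavg(h$counts, h$smoothing_window))]
  } else NA_real_
  out <- lapply(seq_len(k), function(i) {
    iso <- threshold
    if (local_iso) {
      interior <- stats::quantile(vol$values[labels$values == i], 0.9,
                                  names = FALSE)
      cand <- bg + 0.5 * (interior - bg)
      if (cand > bg) iso <- cand
    }
    mesh <- tryCatch(
      isosurface(vol, iso, labels = labels, label = i, pad = pad,
                 presmooth = presmooth),
      error = function(e)
        isosurface(vol, threshold, labels = labels, label = i, pad = pad,
                   presmooth = presmooth))
    area <- mesh_area(mesh)
    volm <- mesh_volume(mesh)
    data.frame(label = i, iso_level = iso, area_nm2 = area, volume_nm3 = volm,
               vssa_m2cm3 = compute_vssa(area, volm)$vssa,
               watertight = is_watertight(mesh))
  })
  do.call(rbind, out)
}
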