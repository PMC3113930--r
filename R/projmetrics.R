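# 2D analysis of the zero-tilt image, replicating the conventional-TEM
# workflow the tomographic measurements are validated against: threshold
# segmentation of the projection, equivalent circle diameter (ECD),
# perfect-sphere surface area and volume from the ECD, and sphericity.

#' Segment particles in the zero-tilt image
#'
#' Selects the minimal-|angle| image of the series, applies a light Gaussian
#' smoothing (shot-noise suppression), thresholds, labels 8-connected
#' regions, removes border-touching regions, despeckles regions below
#' `min_pixels`, and measures each remaining region: pixel count, area in
#' nm^2, ECD, sphericity, and the perfect-sphere surface area and volume
#' computed from the ECD.
#'
#' Thresholding mirrors the per-particle region-of-interest practice of
#' operator-driven 2D analysis.  Background level and noise are estimated by
#' sigma clipping (robust even when particles and their smoothing halos
#' cover most of the image).  Particle seeds come from two detection passes
#' -- a high one (50% of the way from background to the 99.9th percentile)
#' that separates superimposed particles into their bright cores, and a low
#' one (20%) that catches dimmer isolated particles -- and each seed is then
#' grown at a threshold of 20% of its own peak thickness (floored at three
#' noise standard deviations; despeckling handles the rare false
#' positives); pixels contested between grown regions go to the nearer
#' seed.  The low per-particle fraction matters because a projected sphere's
#' thickness tapers to zero at its rim: midpoint criteria such as Otsu's
#' shave the rim and bias the ECD low by 1-2 px, while a global fraction
#' over-thresholds everything whenever superimposed projections double the
#' image maximum.  With this rule, diameters of isolated spheres are
#' recovered within one pixel on noise-free projections.
#'
#' Fully overlapping projections of 3D-separated particles still merge into
#' a single region -- the superposition limitation inherent to 2D projection
#' imaging.  A user-supplied `threshold` disables the local re-growing and
#' reproduces plain single-threshold segmentation.
#'
#' @param ts a [tilt_series].
#' @param threshold optional grey threshold; the fixed-fraction rule above
#'   when `NULL`.
#' @param smooth_sigma Gaussian sigma in px applied before thresholding.
#' @param min_pixels minimum region size in px.
#' @param exclude_border drop regions touching the image border.
#' @return `list(regions = <data.frame>, labels = <integer matrix>,
#'   threshold = <value>)`; regions has columns `label`, `pixel_area`,
#'   `area_nm2`, `ecd_nm`, `sphericity`, `calc_sphere_area_nm2`,
#'   `calc_sphere_volume_nm3`.
#' @export
segment_zero_tilt <- function(ts, threshold = NULL, smooth_sigma = 1.5,
                              min_pixels = 20, exclude_border = TRUE) {
  stopifnot(inherits(ts, "tilt_series"))
  img <- ts$images[, , zero_tilt_index(ts)]
  sm <- gaussian_blur2d(img, smooth_sigma)
  if (min(sm) == max(sm)) stop("blank image: no foreground")
  d <- dim(sm)
  label_at <- function(img2d, thr) {
    mask <- array(as.integer(img2d >= thr), c(1L, dim(img2d)))
    array(cpp_label_components(mask, dim(mask), 26L), dim(mask))[1, , ]
  }
  if (!is.null(threshold)) {
    # plain single-threshold segmentation at the user's value
    lab <- label_at(sm, threshold)
    if (max(lab) == 0) stop("no foreground at this threshold")
  } else {
    # background level and noise by sigma clipping: with many particles
    # plus their smoothing halos, well over half the pixels can be
    # non-background, which breaks one-shot median/MAD statistics
    v <- as.numeric(sm)
    med <- stats::median(v)
    s <- stats::mad(v)
    for (it in 1:4) {
      kp <- abs(v - med) < 3 * s
      if (!any(kp)) break
      med <- stats::median(v[kp])
      s2 <- stats::mad(v[kp])
      if (s2 <= 0) break
      s <- s2
    }
    rmax <- stats::quantile(sm, 0.999, names = FALSE)
    if (rmax <= med) stop("no foreground above the background level")
    # high pass separates superimposed particles into their bright cores;
    # low pass catches dimmer isolated particles the high pass misses
    t_lo <- med + max(0.2 * (rmax - med), 4 * s)
    t_hi <- med + max(0.5 * (rmax - med), 4 * s)
    lab_lo <- label_at(sm, t_lo)
    lab_hi <- label_at(sm, t_hi)
    peaks <- matrix(0L, 0, 2)
    for (k in seq_len(max(lab_hi))) {
      px <- which(lab_hi == k, arr.ind = TRUE)
      if (nrow(px) < 5) next
      peaks <- rbind(peaks, px[which.max(sm[px]), ])
    }
    seeded_lo <- if (nrow(peaks)) unique(lab_lo[peaks]) else integer(0)
    for (k in setdiff(seq_len(max(lab_lo)), seeded_lo)) {
      px <- which(lab_lo == k, arr.ind = TRUE)
      if (nrow(px) < min_pixels) next
      peaks <- rbind(peaks, px[which.max(sm[px]), ])
    }
    if (nrow(peaks) == 0) stop("no foreground at this threshold")
    peaks <- peaks[order(-sm[peaks]), , drop = FALSE]
    # grow each seed at a threshold set by its own peak thickness -- the
    # automated analogue of drawing a per-particle ROI and thresholding it.
    # Where two grown regions share pixels (partially superimposed
    # projections), each contested pixel goes to the nearer seed, so a
    # bridged neighbour is never swallowed whole.
    lab <- array(0L, d)
    bestd <- array(Inf, d)
    for (i in seq_len(nrow(peaks))) {
      pk <- peaks[i, ]
      lo_id <- lab_lo[pk[1], pk[2]]
      px_lo <- which(lab_lo == lo_id, arr.ind = TRUE)
      b1 <- max(min(px_lo[, 1]) - 4, 1); b2 <- min(max(px_lo[, 1]) + 4, d[1])
      b3 <- max(min(px_lo[, 2]) - 4, 1); b4 <- min(max(px_lo[, 2]) + 4, d[2])
      local_thr <- med + max(0.2 * (sm[pk[1], pk[2]] - med), 3 * s)
      sub_lab <- label_at(sm[b1:b2, b3:b4, drop = FALSE], local_thr)
      sl <- sub_lab[pk[1] - b1 + 1, pk[2] - b3 + 1]
      if (sl == 0) next
      grown <- which(sub_lab == sl, arr.ind = TRUE)
      grown[, 1] <- grown[, 1] + b1 - 1L
      grown[, 2] <- grown[, 2] + b3 - 1L
      di <- (grown[, 1] - pk[1])^2 + (grown[, 2] - pk[2])^2
      upd <- di < bestd[grown]
      lab[grown[upd, , drop = FALSE]] <- i
      bestd[grown[upd, , drop = FALSE]] <- di[upd]
    }
    threshold <- t_lo
  }
  n <- max(lab)
  if (n == 0) stop("no foreground at this threshold")
  sizes <- tabulate(lab[lab > 0L], n)
  drop <- sizes < min_pixels
  if (exclude_border) {
    border <- unique(c(lab[c(1, d[1]), ], lab[, c(1, d[2])]))
    drop[border[border > 0L]] <- TRUE
  }
  keep <- which(!drop)
  if (length(keep) == 0)
    stop("no regions remain after border exclusion and despeckling")
  keep <- keep[order(-sizes[keep], keep)]
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out_lab <- array(0L, dim(lab))
  pos <- lab > 0L
  out_lab[pos] <- remap[lab[pos]]
  ps <- ts$pixel_size
  rows <- lapply(seq_along(keep), function(i) {
    px <- which(out_lab == i, arr.ind = TRUE)
    area <- nrow(px) * ps^2
    e <- ecd(area)
    sph <- if (nrow(px) >= 10)
      tryCatch(sphericity(px), error = function(err) NA_real_)
    else NA_real_
    data.frame(label = i, pixel_area = nrow(px), area_nm2 = area, ecd_nm = e,
               sphericity = sph,
               calc_sphere_area_nm2 = sphere_surface_area(e),
               calc_sphere_volume_nm3 = sphere_volume(e))
  })
  list(regions = do.call(rbind, rows), labels = out_lab, threshold = threshold)
}

#' Equivalent circle diameter
#'
#' Diameter of the circle with the same area as the projected particle:
#' `2 * sqrt(area / pi)`.
#'
#' @param area_nm2 projected area in nm^2 (> 0).
#' @return ECD in nm.
#' @export
ecd <- function(area_nm2) {
  if (!is.numeric(area_nm2) || any(area_nm2 <= 0)) stop("`area_nm2` must be > 0")
  2 * sqrt(area_nm2 / pi)
}

#' Perfect-sphere surface area from an ECD
#'
#' `4*pi*(ecd/2)^2`.
#'
#' @param ecd_nm equivalent circle diameter in nm (> 0).
#' @return Area in nm^2.
#' @export
sphere_surface_area <- function(ecd_nm) {
  if (!is.numeric(ecd_nm) || any(ecd_nm <= 0)) stop("`ecd_nm` must be > 0")
  4 * pi * (ecd_nm / 2)^2
}

#' Perfect-sphere volume from an ECD
#'
#' `4/3*pi*(ecd/2)^3`.
#'
#' @inheritParams sphere_surface_area
#' @return Volume in nm^3.
#' @export
sphere_volume <- function(ecd_nm) {
  if (!is.numeric(ecd_nm) || any(ecd_nm <= 0)) stop("`ecd_nm` must be > 0")
  4 / 3 * pi * (ecd_nm / 2)^3
}

#' Sphericity of a projected region from central moments
#'
#' Roundness measure: the square root of the ratio of the smaller to the
#' larger eigenvalue of the 2x2 second-central-moment matrix of the pixel
#' coordinates -- 1 for a disk, `b/a` for an ellipse with semi-axes
#' `a >= b`.  Rotation-invariant.
#'
#' @param px an `n x 2` matrix of pixel coordinates (n >= 10).
#' @return Sphericity in (0, 1].
#' @export
sphericity <- function(px) {
  px <- as.matrix(px)
  if (nrow(px) < 10) stop("region must have at least 10 pixels")
  m <- cov(px)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(1, ev[1]))
    stop("degenerate region (collinear pixels)")
  sqrt(ev[2] / ev[1])
}
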