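# Single-axis bright-field tilt-series simulation under the mass-thickness
# (line-integral) contrast model: missing wedge, shot/readout noise, and
# stage jitter.  Projection values are kept in "thickness" space
# (nm * density) so reconstruction stays linear; the exponential
# intensity model lives only inside add_noise().

#' Tilt series container
#'
#' @param images numeric 3D array `(ny, nx, n_angles)`; one projection image
#'   per tilt angle, rows along the tilt (y) axis.
#' @param angles numeric vector of tilt angles in degrees, strictly
#'   ascending, one per image.
#' @param pixel_size pixel edge in nm (> 0).
#' @param tilt_axis list with `rotation` (in-plane angle of the tilt axis,
#'   deg) and `offset` (offset of the axis from the image centre, px).
#' @param applied_shifts optional `n x 2` matrix of true per-image `(dy, dx)`
#'   stage shifts in px (ground truth for alignment).
#' @return An object of class `tilt_series`.
#' @export
tilt_series <- function(images, angles, pixel_size,
                        tilt_axis = list(rotation = 0, offset = 0),
                        applied_shifts = NULL) {
  if (!is.array(images) || length(dim(images)) != 3L)
    stop("`images` must be a 3D array (ny, nx, n_angles)")
  if (dim(images)[3] != length(angles))
    stop("need exactly one angle per image")
  if (length(angles) > 1 && any(diff(angles) <= 0))
    stop("`angles` must be strictly ascending")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (!is.null(applied_shifts)) {
    applied_shifts <- as.matrix(applied_shifts)
    stopifnot(nrow(applied_shifts) == length(angles), ncol(applied_shifts) == 2)
  }
  structure(list(images = images, angles = as.numeric(angles),
                 pixel_size = pixel_size, tilt_axis = tilt_axis,
                 applied_shifts = applied_shifts),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<tilt_series> %d images %d x %d px @ %.4g nm/px, tilt %g..%g deg\n",
              d[3], d[1], d[2], x$pixel_size, min(x$angles), max(x$angles)))
  invisible(x)
}

n_images <- function(ts) dim(ts$images)[3]

#' Index of the minimal-tilt (nominally zero-degree) image
#' @param ts a [tilt_series].
#' @return Integer index into the image stack.
#' @export
zero_tilt_index <- function(ts) which.min(abs(ts$angles))

#' Acquisition parameters
#'
#' Defaults emulate the routine single-axis protocol: at least +/-65 degrees
#' of tilt at 1 degree intervals.  `dose` is the expected electron count per
#' pixel through vacuum (shot noise); `lambda_nm` the mass-thickness
#' attenuation length of the intensity model `I = dose * exp(-p / lambda)`;
#' `readout_sigma` an additive detector noise sd in counts; `jitter_max` the
#' half-range of the uniform per-image stage shift in px.
#'
#' @param tilt_min,tilt_max tilt range in degrees (`tilt_min < tilt_max`).
#' @param increment tilt step in degrees (> 0).
#' @param dose expected vacuum counts per pixel (>= 0).
#' @param lambda_nm attenuation length (nm).
#' @param readout_sigma additive noise sd (counts, >= 0).
#' @param jitter_max maximum absolute stage shift per axis (px, >= 0).
#' @param seed integer seed for noise and jitter.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tilt_min = -65, tilt_max = 65, increment = 1,
                               dose = 2000, lambda_nm = 300,
                               readout_sigma = 0, jitter_max = 3,
                               seed = 1L) {
  if (tilt_min >= tilt_max) stop("tilt_min must be < tilt_max")
  if (increment <= 0) stop("increment must be > 0")
  if (dose < 0) stop("dose must be >= 0")
  if (jitter_max < 0) stop("jitter_max must be >= 0")
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 increment = increment, dose = dose, lambda_nm = lambda_nm,
                 readout_sigma = readout_sigma, jitter_max = jitter_max,
                 seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Simulate a noise-free tilt series from a volume
#'
#' Each image is the line integral of density along the beam: the volume is
#' rotated about the tilt (y) axis by the negated tilt angle with bilinear
#' interpolation and summed along z, scaled by the voxel size so values are
#' in nm x density.  The tilt axis may be offset from the image centre
#' (`axis_offset`, px) to emulate an uncorrected rotation axis.
#'
#' @param volume a [volume3d].
#' @param params an [acquisition_params()].
#' @param axis_offset tilt-axis offset from the image centre in px.
#' @return A [tilt_series] with one image per angle.
#' @export
project_series <- function(volume, params = acquisition_params(),
                           axis_offset = 0) {
  stopifnot(is_volume3d(volume))
  d <- dim(volume$values)
  if (any(d < 4)) stop("volume too small for rotation padding (all dims must be >= 4)")
  angles <- seq(params$tilt_min, params$tilt_max, by = params$increment)
  imgs <- cpp_project(volume$values, d, angles, axis_offset, volume$voxel_size)
  tilt_series(imgs, angles, volume$voxel_size,
              tilt_axis = list(rotation = 0, offset = axis_offset))
}

#' Add shot and readout noise to a tilt series
#'
#' Thickness values `p` are mapped to bright-field intensities
#' `I = dose * exp(-p / lambda)`, Poisson-sampled (normal approximation
#' above 1e9 expected counts), perturbed by additive Gaussian readout noise,
#' and mapped back through `-lambda * log(I / dose)` so downstream stages
#' still see projection-like values.
#'
#' @param ts a [tilt_series].
#' @param params an [acquisition_params()]; uses `dose`, `lambda_nm`,
#'   `readout_sigma` and `seed`.
#' @return A noisy [tilt_series]; identity (with a warning) when `dose <= 0`
#'   and `readout_sigma == 0`.
#' @export
add_noise <- function(ts, params) {
  stopifnot(inherits(ts, "tilt_series"))
  if (params$dose <= 0 && params$readout_sigma == 0) {
    warning("dose <= 0 with no readout noise: returning the series unchanged")
    return(ts)
  }
  if (params$dose <= 0) stop("shot noise requires dose > 0")
  lam <- params$lambda_nm
  with_seed(params$seed + 70001L, {
    I <- params$dose * exp(-ts$images / lam)
    In <- I
    big <- I > 1e9
    if (any(!big)) In[!big] <- rpois(sum(!big), I[!big])
    if (any(big)) In[big] <- I[big] + sqrt(I[big]) * rnorm(sum(big))
    if (params$readout_sigma > 0)
      In <- In + rnorm(length(In), 0, params$readout_sigma)
    In <- pmax(In, 0.25)  # guard the log for zero-count pixels
    noisy <- -lam * log(In / params$dose)
    dim(noisy) <- dim(ts$images)
  })
  ts$images <- noisy
  ts
}

#' Apply random stage jitter to a tilt series
#'
#' Translates each image by an independent uniform 2-vector in
#' `[-jitter_max, jitter_max]^2` px (bilinear interpolation, zero fill) and
#' records the true shifts in `applied_shifts` as the ground truth that
#' alignment must undo.
#'
#' @param ts a [tilt_series].
#' @param params an [acquisition_params()]; uses `jitter_max` and `seed`.
#' @return The jittered [tilt_series] with `applied_shifts` filled.
#' @export
apply_jitter <- function(ts, params) {
  stopifnot(inherits(ts, "tilt_series"))
  n <- n_images(ts)
  if (params$jitter_max == 0) {
    ts$applied_shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
    return(ts)
  }
  shifts <- with_seed(params$seed + 30011L,
                      matrix(runif(2 * n, -params$jitter_max, params$jitter_max),
                             n, 2, dimnames = list(NULL, c("dy", "dx"))))
  for (i in seq_len(n))
    ts$images[, , i] <- cpp_shift_image(ts$images[, , i],
                                        shifts[i, 1], shifts[i, 2])
  ts$applied_shifts <- shifts
  ts
}

#' Translate every image of a series by per-image shifts
#' @param ts a [tilt_series].
#' @param shifts `n x 2` matrix of `(dy, dx)` px.
#' @return The shifted [tilt_series].
#' @export
shift_series <- function(ts, shifts) {
  stopifnot(inherits(ts, "tilt_series"))
  shifts <- as.matrix(shifts)
  stopifnot(nrow(shifts) == n_images(ts), ncol(shifts) == 2)
  for (i in seq_len(n_images(ts)))
    if (shifts[i, 1] != 0 || shifts[i, 2] != 0)
      ts$images[, , i] <- cpp_shift_image(ts$images[, , i],
                                          shifts[i, 1], shifts[i, 2])
  ts
}
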