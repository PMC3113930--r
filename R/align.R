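# Translational tilt-series alignment by iterative cross-correlation along
# the neighbour chain anchored at the zero-tilt image, plus tilt-axis offset
# refinement by minimizing reconstruction negativity (streak energy).

# frequency-domain difference-of-Gaussians transfer used to suppress shot
# noise (small sigma) and slow illumination gradients (large sigma) before
# correlation
bandpass_transfer <- function(d, sigma_lo = 1, sigma_hi = 10) {
  tf <- function(n, sigma) {
    f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  }
  outer(tf(d[1], sigma_lo), tf(d[2], sigma_lo)) -
    outer(tf(d[1], sigma_hi), tf(d[2], sigma_hi))
}

#' Register one image against a reference by cross-correlation
#'
#' Returns the translation `(dy, dx)` in px that `moving` has undergone
#' relative to `reference`, i.e. `moving ~ reference translated by (dy, dx)`;
#' shifting `moving` by the negated result aligns it.  The integer
#' cross-correlation peak (FFT-based, optionally band-pass filtered) is
#' refined to subpixel precision by a separable parabolic fit.
#'
#' @param reference,moving equal-size numeric matrices, non-constant.
#' @param bandpass apply the soft band-pass pre-filter (default `TRUE`).
#' @param max_shift largest shift magnitude considered per axis (px);
#'   defaults to a quarter of the smaller image dimension.
#' @return Numeric `(dy, dx)`.
#' @export
register_pair <- function(reference, moving, bandpass = TRUE,
                          max_shift = NULL) {
  if (!identical(dim(reference), dim(moving)))
    stop("`reference` and `moving` must have equal shapes")
  if (sd(reference) == 0 || sd(moving) == 0)
    stop("constant image: zero-variance correlation undefined")
  d <- dim(reference)
  if (is.null(max_shift)) max_shift <- floor(min(d) / 4)
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  fa <- fft(a); fb <- fft(b)
  prod <- Conj(fa) * fb
  if (bandpass) {
    h <- bandpass_transfer(d)
    prod <- prod * h * h
  }
  cc <- Re(fft(prod, inverse = TRUE)) / prod(d)
  # wrap index u (0-based) to signed shift
  sy <- c(0:(d[1] - 1)); sy[sy > d[1] / 2] <- sy[sy > d[1] / 2] - d[1]
  sx <- c(0:(d[2] - 1)); sx[sx > d[2] / 2] <- sx[sx > d[2] / 2] - d[2]
  ok <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift)
  cc_m <- cc
  cc_m[!ok] <- -Inf
  pk <- arrayInd(which.max(cc_m), d)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) return(0)  # not a proper maximum; skip refinement
    max(min(0.5 * (cm - cp) / den, 0.5), -0.5)
  }
  dy <- sy[pk[1]] + para(cc[wrap(pk[1] - 1, d[1]), pk[2]],
                         cc[pk[1], pk[2]],
                         cc[wrap(pk[1] + 1, d[1]), pk[2]])
  dx <- sx[pk[2]] + para(cc[pk[1], wrap(pk[2] - 1, d[2])],
                         cc[pk[1], pk[2]],
                         cc[pk[1], wrap(pk[2] + 1, d[2])])
  c(dy = dy, dx = dx)
}

#' Align a tilt series by iterative cross-correlation
#'
#' Each iteration registers every image against its neighbour of lower
#' absolute tilt, accumulates the pairwise shifts outward from the zero-tilt
#' anchor, re-shifts the original images by the accumulated totals, and
#' repeats until the mean shift update falls below `tol` (the operational
#' reading of "iterating until the shifts approach zero") or `max_iter` is
#' reached.  Because a translation-only chain cannot observe the absolute
#' shift of the anchor image, the series mean of the estimated shifts is
#' removed, keeping the field of view centred.
#'
#' @param ts a [tilt_series] with at least 2 images.
#' @param max_iter maximum number of iterations (default 10).
#' @param tol convergence tolerance on the mean shift update in px (> 0).
#' @param bandpass passed to [register_pair()].
#' @return `list(series = <aligned tilt_series>, result = <alignment_result>)`
#'   where the result holds `shifts` (the estimated per-image drift; the
#'   aligned series is the original shifted by `-shifts`), `axis_offset`,
#'   `axis_rotation`, `residual_history` (mean absolute shift update per
#'   iteration), `n_iterations` and `converged`.
#' @export
align_series <- function(ts, max_iter = 10, tol = 0.5, bandpass = TRUE) {
  stopifnot(inherits(ts, "tilt_series"))
  n <- n_images(ts)
  if (n < 2) stop("need at least 2 images to align")
  if (tol <= 0) stop("`tol` must be > 0")
  anchor <- zero_tilt_index(ts)
  neighbour <- ifelse(seq_len(n) < anchor, seq_len(n) + 1L, seq_len(n) - 1L)
  order_out <- order(abs(seq_len(n) - anchor))  # anchor first, then outward
  total <- matrix(0, n, 2)
  history <- numeric(0)
  converged <- FALSE
  current <- ts$images
  for (iter in seq_len(max_iter)) {
    delta <- matrix(0, n, 2)
    for (i in order_out) {
      if (i == anchor) next
      d <- register_pair(current[, , neighbour[i]], current[, , i],
                         bandpass = bandpass)
      delta[i, ] <- delta[neighbour[i], ] + d
    }
    history <- c(history, mean(sqrt(rowSums(delta^2))))
    total <- total + delta
    for (i in seq_len(n))
      current[, , i] <- cpp_shift_image(ts$images[, , i],
                                        -total[i, 1], -total[i, 2])
    if (history[iter] < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("alignment did not converge in %d iterations (last mean update %.3f px)",
                    max_iter, tail(history, 1)))
  # Gauge fixing: in single-axis geometry a per-image shift of the form
  # a + b*sin(theta) + c*cos(theta) along x (perpendicular to the tilt
  # axis), or a constant along y, merely translates the reconstructed
  # object.  A chain of pairwise registrations accumulates exactly such a
  # smooth component from particles sitting off the rotation axis; it is
  # unobservable and is projected out, leaving the jitter estimate.
  th <- ts$angles * pi / 180
  basis <- cbind(1, sin(th), cos(th))
  total[, 2] <- stats::lm.fit(basis, total[, 2])$residuals
  total[, 1] <- total[, 1] - mean(total[, 1])
  aligned <- ts
  for (i in seq_len(n))
    aligned$images[, , i] <- cpp_shift_image(ts$images[, , i],
                                             -total[i, 1], -total[i, 2])
  colnames(total) <- c("dy", "dx")
  result <- structure(list(shifts = total, axis_offset = 0, axis_rotation = 0,
                           residual_history = history,
                           n_iterations = length(history),
                           converged = converged),
                      class = "alignment_result")
  list(series = aligned, result = result)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d iterations, %s; mean |shift| %.2f px\n",
              x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              mean(sqrt(rowSums(x$shifts^2)))))
  invisible(x)
}

#' Refine the tilt-axis offset of an aligned series
#'
#' Estimates the in-plane offset of the rotation axis from the mass
#' centroid of the projections: for a rotation axis at offset `o` from the
#' image centre, the x centroid of the projected mass follows
#' `o + b cos(theta) + c sin(theta)` over the tilt angles, where `b` and
#' `c` encode the (unknown) specimen centre.  A least-squares fit of that
#' three-parameter model to the per-angle sinogram centroids therefore
#' yields the axis offset as its constant term, to subpixel precision and
#' deterministically.  An uncorrected offset bends every feature into an
#' arc, producing the streak artifacts and particle elongation this
#' refinement exists to remove.
#'
#' @param ts an aligned [tilt_series].
#' @param search_range plausibility bound on |offset| in px (> 0); estimates
#'   beyond it are clamped with a warning.
#' @param n_rows number of central image rows averaged into the working
#'   sinogram.
#' @return The estimated axis offset in px.
#' @export
refine_tilt_axis <- function(ts, search_range = 5, n_rows = 8) {
  stopifnot(inherits(ts, "tilt_series"))
  if (search_range <= 0) stop("`search_range` must be > 0")
  d <- dim(ts$images)
  rows <- seq(max(1, floor(d[1] / 2) - n_rows %/% 2),
              length.out = min(n_rows, d[1]))
  sino <- apply(ts$images[rows, , , drop = FALSE], c(2, 3), mean)  # nx x na
  cx <- (d[2] - 1) / 2
  centroids <- apply(sino, 2, function(p) {
    p <- pmax(p, 0)                      # suppress negative noise excursions
    if (sum(p) <= 0) return(NA_real_)
    sum((seq_along(p) - 1 - cx) * p) / sum(p)
  })
  ok <- is.finite(centroids)
  if (sum(ok) < 3) stop("not enough usable projections to fit the tilt axis")
  th <- ts$angles[ok] * pi / 180
  fit <- stats::lm.fit(cbind(1, cos(th), sin(th)), centroids[ok])
  off <- unname(fit$coefficients[1])
  if (abs(off) > search_range) {
    warning(sprintf("estimated axis offset %.2f px exceeds search_range; clamped", off))
    off <- sign(off) * search_range
  }
  off
}
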