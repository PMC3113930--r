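# Grey-value segmentation of reconstructions: histogram, bimodal-valley and
# Otsu thresholds, 2x2x2 smoothing/downsampling, and 3D connected-component
# particle labelling.

#' Grey-value histogram of a volume
#'
#' @param vol a non-constant [volume3d].
#' @param n_bins number of bins (>= 16; default 256).
#' @return An object of class `grey_histogram` with `bin_edges` (length
#'   `n_bins + 1`), `counts` and `smoothing_window` (bins, used by
#'   [valley_threshold()]).
#' @export
grey_histogram <- function(vol, n_bins = 256) {
  stopifnot(is_volume3d(vol))
  if (n_bins < 16) stop("`n_bins` must be >= 16")
  v <- as.numeric(vol$values)
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("constant volume: no threshold definable")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(floor((v - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  structure(list(bin_edges = edges, counts = tabulate(idx, n_bins),
                 smoothing_window = 5L),
            class = "grey_histogram")
}

bin_centres <- function(hist)
  (head(hist$bin_edges, -1) + tail(hist$bin_edges, -1)) / 2

# moving average with replicated-edge padding
movavg <- function(x, w) {
  if (w <= 1) return(x)
  k <- w %/% 2
  xp <- c(rep(x[1], k), x, rep(x[length(x)], k))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[k + seq_along(x)]
}

# indices of local maxima, plateau-aware (middle of each maximal run);
# boundaries count as maxima only against their single inner neighbour
local_maxima <- function(s) {
  r <- rle(s)
  n <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer(0)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == n || r$values[i + 1] < r$values[i]
    if (left_ok && right_ok)
      out <- c(out, (starts[i] + ends[i]) %/% 2)
  }
  out
}

#' Bimodal-valley threshold
#'
#' The single-threshold rule used for reconstructions with a bimodal grey
#' histogram: the threshold is the minimum of the smoothed histogram
#' strictly between its two peaks.  The histogram is smoothed with a moving
#' average of `smoothing_window` bins, repeatedly (scale-space fashion)
#' until at most two local maxima remain, which makes the valley
#' well-defined on noisy reconstruction histograms.  Ties are broken toward
#' the lower grey value.  Deterministic.
#'
#' @param hist a [grey_histogram()].
#' @return The threshold grey value (a bin centre).
#' @export
valley_threshold <- function(hist) {
  stopifnot(inherits(hist, "grey_histogram"))
  # peaks are found on log counts: particle voxels are a tiny fraction of a
  # reconstruction, and on a linear scale their mode is drowned by count
  # fluctuations of the huge background peak
  s <- movavg(log1p(hist$counts), hist$smoothing_window)
  # ignore peaks of negligible prominence (< 20% of the tallest peak on the
  # log scale): a genuine mode must clear the count-noise floor -- bins
  # holding only 2-3 voxels while the background peak holds thousands are
  # plateau remnants of under-resolved particles, not modes
  prominent <- function(s) {
    p <- local_maxima(s)
    p[s[p] >= 0.2 * max(s)]
  }
  peaks <- prominent(s)
  passes <- 0
  while (length(peaks) > 2 && passes < 200) {
    s <- movavg(s, hist$smoothing_window)
    peaks <- prominent(s)
    passes <- passes + 1
  }
  if (length(peaks) < 2 || diff(range(peaks)) < 2)
    stop("histogram is not bimodal after smoothing; use otsu_threshold() or halfmax_threshold()")
  p <- sort(peaks)
  between <- (p[1] + 1):(p[2] - 1)
  valley <- between[which.min(s[between])]  # which.min ties -> lower bin
  cen <- bin_centres(hist)
  # two genuine modes are well separated and the count actually dips
  # between them; wiggles on a single mode satisfy neither
  win <- function(i) max(1, i - 2):min(length(hist$counts), i + 2)
  peak_raw <- c(max(hist$counts[win(p[1])]), max(hist$counts[win(p[2])]))
  valley_raw <- min(hist$counts[win(valley)])
  if ((cen[p[2]] - cen[p[1]]) < 0.15 * diff(range(cen)) ||
      valley_raw > 0.6 * min(peak_raw))
    stop("histogram is not bimodal after smoothing (no distinct valley between well-separated modes); use otsu_threshold() or halfmax_threshold()")
  # sanity: a usable valley separates background from particle interior.
  # When the foreground mode is too weak (under-resolved particles), the
  # detected valley drifts into the foreground flank; reject it there
  # (above 60% of the way from the background mode to the 99.9th
  # percentile) rather than cut through the particle.
  cum <- cumsum(hist$counts) / sum(hist$counts)
  q999 <- cen[which(cum >= 0.999)[1]]
  if ((cen[valley] - cen[p[1]]) > 0.6 * (q999 - cen[p[1]]))
    stop("histogram valley lies in the foreground flank (foreground mode too weak); use halfmax_threshold()")
  cen[valley]
}

# between-class-variance scan shared by otsu_threshold and the 2D
# segmentation; returns the threshold (bin edge between the two classes)
otsu_core <- function(values, n_bins = 256) {
  lo <- min(values); hi <- max(values)
  if (lo == hi) stop("constant input: no threshold definable")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, n_bins)
  p <- counts / sum(counts)
  centres <- (head(edges, -1) + tail(edges, -1)) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centres)
  mu_t <- mu[n_bins]
  t_range <- seq_len(n_bins - 1)
  w0t <- w0[t_range]
  valid <- w0t > 0 & w0t < 1
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mu_t * w0t[valid] - mu[t_range][valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  k <- which.max(bcv)  # ties -> lower
  edges[k + 1]
}

#' Half-maximum threshold
#'
#' Fallback for histograms that are not bimodal (e.g. a single small,
#' blurred particle occupying a fraction of a percent of the volume, whose
#' grey values ramp without a distinct mode): the threshold is placed midway
#' between the background mode (the histogram peak) and a robust maximum
#' (the 99.9th percentile, which ignores isolated hot voxels).  This is the
#' fixed-fraction criterion familiar from full-width-half-maximum particle
#' sizing.
#'
#' @param vol a non-constant [volume3d].
#' @param fraction position between background mode and robust maximum
#'   (default 0.5).
#' @return The threshold grey value.
#' @export
halfmax_threshold <- function(vol, fraction = 0.5) {
  stopifnot(is_volume3d(vol))
  h <- grey_histogram(vol)
  s <- movavg(h$counts, h$smoothing_window)
  bg <- bin_centres(h)[which.max(s)]
  rmax <- stats::quantile(vol$values, 0.999, names = FALSE)
  if (rmax <= bg) stop("no grey values above the background mode")
  bg + fraction * (rmax - bg)
}

#' Otsu threshold of a volume
#'
#' Maximizes the between-class variance of the grey histogram; the automatic
#' alternative when the histogram valley is ill-defined.  Invariant (up to
#' the same affine map) under affine intensity rescaling.
#'
#' @param vol a non-constant [volume3d].
#' @param n_bins number of histogram bins.
#' @return The threshold grey value.
#' @export
otsu_threshold <- function(vol, n_bins = 256) {
  stopifnot(is_volume3d(vol))
  otsu_core(as.numeric(vol$values), n_bins)
}

#' 2x2x2 averaging downsample
#'
#' Block-mean smoothing used to reduce missing-wedge streaks before surface
#' creation; each output voxel is the mean of a 2x2x2 input block and the
#' voxel size doubles.  Odd trailing planes are dropped (with a message).
#'
#' @param vol a [volume3d] with all dimensions >= 2.
#' @return The downsampled [volume3d].
#' @export
smooth_downsample <- function(vol) {
  stopifnot(is_volume3d(vol))
  d <- dim(vol$values)
  if (any(d < 2)) stop("all dimensions must be >= 2 to downsample")
  keep <- d - d %% 2L
  if (any(keep < d))
    message(sprintf("dropping odd trailing plane(s): %s -> %s",
                    paste(d, collapse = "x"), paste(keep, collapse = "x")))
  v <- vol$values[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), drop = FALSE]
  o1 <- seq(1, keep[1], 2); o2 <- seq(1, keep[2], 2); o3 <- seq(1, keep[3], 2)
  out <- (v[o1, o2, o3, drop = FALSE] + v[o1 + 1, o2, o3, drop = FALSE] +
          v[o1, o2 + 1, o3, drop = FALSE] + v[o1 + 1, o2 + 1, o3, drop = FALSE] +
          v[o1, o2, o3 + 1, drop = FALSE] + v[o1 + 1, o2, o3 + 1, drop = FALSE] +
          v[o1, o2 + 1, o3 + 1, drop = FALSE] + v[o1 + 1, o2 + 1, o3 + 1, drop = FALSE]) / 8
  dim(out) <- keep %/% 2L
  volume3d(out, vol$voxel_size * 2, vol$origin)
}

#' Label particles by 3D connected components
#'
#' Voxels at or above `threshold` form the foreground; components are
#' labelled with 26-connectivity by default (silica subunits touch
#' obliquely), components touching the volume boundary are removed when
#' `exclude_border` is set, and components below `min_voxels` voxels are
#' despeckled.  Remaining labels are renumbered 1..K by decreasing size
#' (ties by scan order), which makes labelling deterministic.
#'
#' @param vol a [volume3d].
#' @param threshold foreground threshold (within the volume's value range).
#' @param exclude_border drop components touching any volume face.
#' @param min_voxels minimum component size in voxels (default 30).
#' @param connectivity 26 (default) or 6.
#' @return An object of class `label_volume`: integer array `values`
#'   (0 background, 1..K particles), `voxel_size`, `origin`, `sizes`
#'   (voxel count per label) and `border_excluded`.
#' @export
label_components <- function(vol, threshold, exclude_border = FALSE,
                             min_voxels = 30, connectivity = 26) {
  stopifnot(is_volume3d(vol), connectivity %in% c(6, 26))
  v <- vol$values
  if (threshold < min(v) || threshold > max(v))
    stop("`threshold` lies outside the volume's value range")
  mask <- array(as.integer(v >= threshold), dim(v))
  if (sum(mask) == 0) stop("empty foreground at this threshold")
  labels <- cpp_label_components(mask, dim(v), as.integer(connectivity))
  n <- attr(labels, "n_labels")
  sizes <- tabulate(labels[labels > 0L], n)
  drop <- rep(FALSE, n)
  if (exclude_border) {
    d <- dim(v)
    border <- unique(c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ],
                       labels[, , c(1, d[3])]))
    drop[border[border > 0L]] <- TRUE
  }
  drop[sizes < min_voxels] <- TRUE
  keep <- which(!drop)
  if (length(keep) == 0)
    stop("no components remain after border exclusion and despeckling")
  keep <- keep[order(-sizes[keep], keep)]
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(v))
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  structure(list(values = out, voxel_size = vol$voxel_size,
                 origin = vol$origin, sizes = sizes[keep],
                 border_excluded = exclude_border),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d particle(s), sizes: %s\n",
              paste(dim(x$values), collapse = "x"), length(x$sizes),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Number of labelled particles
#' @param labels a `label_volume`.
#' @return Integer count.
#' @export
n_labels <- function(labels) length(labels$sizes)
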