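#' 3D scalar volume with isotropic voxel size
#'
#' The common container for phantoms, reconstructions and binary masks.
#' Values are stored as a 3D array indexed `[z, y, x]`, where `z` is the
#' electron-beam direction at zero tilt and `y` the tilt axis.  The centre of
#' voxel `(i, j, k)` (1-based) lies at `origin + (c(i, j, k) - 0.5) *
#' voxel_size` in nanometres.
#'
#' @param values numeric 3D array, dimension `(nz, ny, nx)`.
#' @param voxel_size isotropic voxel edge length in nm (> 0).
#' @param origin 3-vector (nm), position of the low corner of the grid.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (nm)")
  if (any(dim(values) < 1L)) stop("all three dimensions must be >= 1")
  if (!all(is.finite(values))) stop("density values must be finite")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x) @ %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

is_volume3d <- function(x) inherits(x, "volume3d")

#' Gaussian blur of a volume
#'
#' Frequency-domain isotropic Gaussian filter, used to emulate resolution
#' loss (e.g. when studying how limited resolution depresses measured VSSA).
#' The volume is zero-padded by `4 * sigma` voxels on each side before the
#' FFT so periodic wrap-around is negligible.
#'
#' @param vol a [volume3d].
#' @param sigma standard deviation of the Gaussian in voxels (>= 0).
#' @return A blurred [volume3d] on the same grid.
#' @export
gaussian_blur3d <- function(vol, sigma) {
  stopifnot(is_volume3d(vol), sigma >= 0)
  if (sigma == 0) return(vol)
  v <- vol$values
  d <- dim(v)
  pad <- ceiling(4 * sigma)
  dp <- d + 2L * pad
  vp <- array(0, dp)
  vp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- v
  tf <- function(n) {
    f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  }
  g <- outer(outer(tf(dp[1]), tf(dp[2])), tf(dp[3]))
  dim(g) <- dp
  sm <- Re(fft(fft(vp) * g, inverse = TRUE)) / prod(dp)
  out <- sm[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
  dim(out) <- d
  volume3d(out, vol$voxel_size, vol$origin)
}

#' Gaussian blur of a 2D image (internal helper)
#' @noRd
gaussian_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  d <- dim(img)
  pad <- ceiling(4 * sigma)
  dp <- d + 2L * pad
  ip <- matrix(0, dp[1], dp[2])
  ip[pad + seq_len(d[1]), pad + seq_len(d[2])] <- img
  tf <- function(n) {
    f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  }
  g <- outer(tf(dp[1]), tf(dp[2]))
  sm <- Re(fft(fft(ip) * g, inverse = TRUE)) / prod(dp)
  sm[pad + seq_len(d[1]), pad + seq_len(d[2])]
}
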