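# MRC2014 I/O (mode 2, float32, little-endian) for volumes and tilt stacks,
# plus STL/PLY mesh writers.  Tilt metadata (angles, pixel size, tilt axis,
# applied shifts) lives in a JSON sidecar "<path>.json" next to the stack --
# simpler and dialect-free compared with MRC extended headers.
# Cell dimensions are stored in Angstrom (nm * 10) per MRC convention.

mrc_write_header <- function(con, nxyz, voxel_nm, dmin, dmax, dmean, rms,
                             is_volume) {
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(nxyz)                      # nx, ny, nz
  wi(2L)                        # mode 2: float32
  wi(c(0L, 0L, 0L))             # nxstart
  wi(nxyz)                      # mx, my, mz
  wf(nxyz * voxel_nm * 10)      # cella (Angstrom)
  wf(c(90, 90, 90))             # cellb
  wi(c(1L, 2L, 3L))             # mapc, mapr, maps
  wf(c(dmin, dmax, dmean))
  wi(if (is_volume) 1L else 0L) # ispg: 1 volume, 0 image stack
  wi(0L)                        # nsymbt
  wi(rep(0L, 25))               # extra
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(rms)
  wi(1L)                        # nlabl
  lab <- "Created by nanovssa"
  writeChar(sprintf("%-80s", lab), con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, nchars = 80 * 9, eos = NULL)
}

#' Write a volume or tilt series as MRC
#'
#' Volumes are written with x fastest, then y, then z (sections); tilt
#' stacks with one section per image in angle order, plus a JSON sidecar
#' `<path>.json` holding `angles`, `pixel_size`, `tilt_axis` and
#' `applied_shifts`.  Mode 2 (float32), little-endian, cell size in
#' Angstrom.
#'
#' @param x a [volume3d] or [tilt_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is_volume3d(x)) {
    d <- dim(x$values)                     # (nz, ny, nx)
    dat <- aperm(x$values, c(3, 2, 1))     # file order: x, y, z
    nxyz <- c(d[3], d[2], d[1])
    voxel <- x$voxel_size
    is_vol <- TRUE
  } else if (inherits(x, "tilt_series")) {
    d <- dim(x$images)                     # (ny, nx, na)
    dat <- aperm(x$images, c(2, 1, 3))     # file order: x, y, section
    nxyz <- c(d[2], d[1], d[3])
    voxel <- x$pixel_size
    is_vol <- FALSE
    sidecar <- list(angles = x$angles, pixel_size = x$pixel_size,
                    tilt_axis = x$tilt_axis,
                    applied_shifts = if (is.null(x$applied_shifts)) NULL
                                     else unname(x$applied_shifts))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    stop("`x` must be a volume3d or tilt_series")
  }
  v <- as.numeric(dat)
  mrc_write_header(con, nxyz, voxel, min(v), max(v), mean(v), sd(v), is_vol)
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC file as a volume or tilt series
#'
#' Mode 2 files only (other modes are rejected by name).  If a JSON sidecar
#' `<path>.json` is present (or `what = "tilt_series"`), the stack is
#' returned as a [tilt_series] using the sidecar's angles and pixel size;
#' otherwise as a [volume3d] with the voxel size from the header.
#'
#' @param path MRC file path.
#' @param what `"auto"` (default), `"volume"` or `"tilt_series"`.
#' @return A [volume3d] or [tilt_series].
#' @export
read_mrc <- function(path, what = c("auto", "volume", "tilt_series")) {
  what <- match.arg(what)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  if (mode != 2)
    stop(sprintf("unsupported MRC mode %d (only mode 2, float32, is supported)", mode))
  ri(3)                       # nxstart
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3)         # cellb, map axes, dmin/dmax/dmean
  ri(1)                       # ispg
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- prod(nxyz)
  v <- rf(n)
  if (length(v) < n)
    stop(sprintf("truncated MRC file: expected %d values, read %d", n, length(v)))
  voxel <- cella[1] / mxyz[1] / 10  # Angstrom -> nm
  dat <- aperm(array(v, nxyz), c(3, 2, 1))  # back to (nz|na, ny, nx)... see below
  sidecar_path <- paste0(path, ".json")
  want_ts <- what == "tilt_series" ||
    (what == "auto" && file.exists(sidecar_path))
  if (want_ts) {
    if (!file.exists(sidecar_path))
      stop(sprintf("missing tilt-series sidecar %s (expected keys: angles, pixel_size, tilt_axis, applied_shifts)",
                   sidecar_path))
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!all(c("angles", "pixel_size") %in% names(sc)))
      stop("invalid sidecar: expected keys angles, pixel_size, tilt_axis, applied_shifts")
    imgs <- aperm(array(v, nxyz), c(2, 1, 3))  # (ny, nx, na)
    tilt_series(imgs, as.numeric(sc$angles), as.numeric(sc$pixel_size),
                tilt_axis = if (!is.null(sc$tilt_axis)) sc$tilt_axis
                            else list(rotation = 0, offset = 0),
                applied_shifts = if (is.null(sc$applied_shifts)) NULL
                  else if (is.matrix(sc$applied_shifts)) sc$applied_shifts
                  else matrix(unlist(sc$applied_shifts), ncol = 2, byrow = TRUE))
  } else {
    volume3d(dat, voxel)
  }
}

#' Write a mesh as binary STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  f <- mesh$faces
  v <- mesh$vertices
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    p0 <- v[f[i, 1], ]; p1 <- v[f[i, 2], ]; p2 <- v[f[i, 3], ]
    nn <- c((p1[2] - p0[2]) * (p2[3] - p0[3]) - (p1[3] - p0[3]) * (p2[2] - p0[2]),
            (p1[3] - p0[3]) * (p2[1] - p0[1]) - (p1[1] - p0[1]) * (p2[3] - p0[3]),
            (p1[1] - p0[1]) * (p2[2] - p0[2]) - (p1[2] - p0[2]) * (p2[1] - p0[1]))
    len <- sqrt(sum(nn^2))
    if (len > 0) nn <- nn / len
    writeBin(as.numeric(c(nn, p0, p1, p2)), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a mesh as ASCII PLY
#'
#' @inheritParams write_mesh_stl
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  body_v <- sprintf("%.6g %.6g %.6g", v[, 1], v[, 2], v[, 3])
  body_f <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, body_v, body_f), path)
  invisible(path)
}
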