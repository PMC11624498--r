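#' Dual-frequency-band RSOM volume
#'
#' Container for a pair of co-registered 3D intensity grids reconstructed from
#' the low (10-40 MHz, larger microvessels) and high (40-120 MHz, smaller
#' microvessels) ultrasound frequency bands of an RSOM scan. Arrays are stored
#' in `(z, y, x)` order with `z = 1` at the top of the field of view and depth
#' increasing into the skin; all geometry is in micrometres.
#'
#' @param low,high 3D numeric arrays of identical dimension, non-negative.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres, all positive.
#'   A single value is recycled to an isotropic grid.
#' @return An object of class `dual_band_volume`: a list with elements `low`,
#'   `high` (numeric arrays) and `spacing`.
#' @examples
#' v <- dual_band_volume(array(0, c(8, 8, 8)), array(0, c(8, 8, 8)))
#' dim(v$low)
#' @export
dual_band_volume <- function(low, high, spacing = c(10, 10, 10)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  low <- array(as.double(low), dim(low))
  high <- array(as.double(high), dim(high))
  v <- structure(list(low = low, high = high,
                      spacing = as.double(spacing)),
                 class = "dual_band_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  if (!identical(dim(v$low), dim(v$high)))
    stop_rv("band shapes differ: (%s) vs (%s)",
            paste(dim(v$low), collapse = "x"),
            paste(dim(v$high), collapse = "x"))
  if (length(dim(v$low)) != 3L)
    stop_rv("bands must be 3D arrays")
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) ||
      any(v$spacing <= 0))
    stop_rv("spacing must be three positive values (dz, dy, dx) in um")
  if (any(v$low < 0, na.rm = TRUE) || any(v$high < 0, na.rm = TRUE))
    stop_rv("intensities must be non-negative")
  invisible(v)
}

#' @export
print.dual_band_volume <- function(x, ...) {
  cat(sprintf("<dual_band_volume> %s voxels, spacing (%g, %g, %g) um\n",
              paste(dim(x$low), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read / write dual-band volumes
#'
#' Two on-disk layouts are supported. `format = "tiff"`: one multi-page TIFF
#' holding `2 * nz` 16-bit pages, the first `nz` pages being the low band and
#' the last `nz` the high band (z-slices as `ny x nx` matrices); integer
#' intensities in `[0, 65535]` round-trip exactly. TIFF carries no reliable
#' 3D spacing metadata, so `spacing` must be supplied on read (default 10 um
#' isotropic). `format = "nifti"`: a single NIfTI-1 file with a 4D array
#' `(z, y, x, band)` and voxel spacing in the header (`pixdim`), stored as
#' float64, so floating-point intensities round-trip as well.
#'
#' @param path file path.
#' @param format `"tiff"` or `"nifti"`; default guessed from the extension.
#' @param spacing spacing override in um; mandatory semantics for TIFF,
#'   overrides the header for NIfTI when non-`NULL`.
#' @param v a [dual_band_volume()].
#' @return `read_volume` returns a [dual_band_volume()]; `write_volume`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, format = NULL, spacing = NULL) {
  if (!file.exists(path)) stop_rv("file not found: %s", path)
  format <- format %||% guess_format(path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    n <- length(pages)
    if (n < 2L || n %% 2L != 0L)
      stop_rv("expected an even number of pages (two bands): got %d", n)
    nz <- n %/% 2L
    d <- dim(pages[[1]])
    low <- array(0, c(nz, d[1], d[2]))
    high <- array(0, c(nz, d[1], d[2]))
    for (z in seq_len(nz)) {
      low[z, , ] <- pages[[z]]
      high[z, , ] <- pages[[nz + z]]
    }
    # pages are stored as [0,1] fractions of the 16-bit range
    low <- round(low * 65535)
    high <- round(high * 65535)
    spacing <- spacing %||% c(10, 10, 10)
    dual_band_volume(low, high, spacing)
  } else if (format == "nifti") {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 4L || dim(a)[4] != 2L)
      stop_rv("expected a 4D NIfTI with 2 bands in the 4th dimension; got dim (%s)",
              paste(dim(a), collapse = "x"))
    sp <- spacing %||% RNifti::pixdim(img)[1:3]
    if (any(sp <= 0)) stop_rv("non-positive voxel spacing: (%s)",
                              paste(sp, collapse = ", "))
    dual_band_volume(a[, , , 1], a[, , , 2], sp)
  } else stop_rv("unknown format '%s'", format)
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path, format = NULL) {
  validate_volume(v)
  format <- format %||% guess_format(path)
  if (format == "tiff") {
    mx <- max(v$low, v$high)
    if (mx > 65535)
      stop_rv("TIFF layout stores 16-bit integers; max intensity %g > 65535", mx)
    nz <- dim(v$low)[1]
    pages <- vector("list", 2L * nz)
    for (z in seq_len(nz)) {
      pages[[z]] <- v$low[z, , ] / 65535
      pages[[nz + z]] <- v$high[z, , ] / 65535
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (format == "nifti") {
    a <- array(0, c(dim(v$low), 2L))
    a[, , , 1] <- v$low
    a[, , , 2] <- v$high
    img <- RNifti::asNifti(a)
    img <- RNifti::`pixdim<-`(img, c(v$spacing, 1))
    RNifti::writeNifti(img, path, datatype = "double")
  } else stop_rv("unknown format '%s'", format)
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
  else stop_rv("cannot guess format from '%s'; pass format=", path)
}

#' Green-yellow-red dual-band composite
#'
#' Maximum-intensity projection of both bands along a lateral axis, colorized
#' so the low band (larger microvessels) maps to the red channel and the high
#' band (smaller microvessels) to the green channel, each min-max scaled;
#' voxels where both bands project strongly render yellow. The blue channel is
#' zero. Projecting along `y` (axis 2) gives the customary cross-sectional
#' side view with depth running down the image.
#'
#' @param v a [dual_band_volume()].
#' @param projection_axis lateral axis to collapse: 2 (`y`) or 3 (`x`).
#' @return numeric array `h x w x 3` of RGB values in `[0, 1]`.
#' @export
render_composite <- function(v, projection_axis = 2L) {
  validate_volume(v)
  if (!projection_axis %in% c(2L, 3L))
    stop_rv("projection_axis must be 2 (y) or 3 (x); depth is never collapsed")
  keep <- setdiff(1:3, projection_axis)
  mip <- function(a) apply(a, keep, max)
  r <- mip(v$low)
  g <- mip(v$high)
  scale01 <- function(m) {
    lo <- min(m); hi <- max(m)
    if (hi > lo) (m - lo) / (hi - lo) else m * 0
  }
  out <- array(0, c(dim(r), 3L))
  out[, , 1] <- scale01(r)
  out[, , 2] <- scale01(g)
  out
}
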