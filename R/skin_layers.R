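#' Detect the skin surface depth map
#'
#' For every lateral column the two bands are summed into a depth profile and
#' the surface is placed at the first sustained intensity rise: the first
#' voxel at which the profile stays above `rise_frac` times the volume's
#' robust maximum for `sustain` consecutive voxels. Columns with no signal
#' are filled from the lateral median, and the map is median-smoothed with a
#' `smooth_window` square kernel.
#'
#' @param v a [dual_band_volume()].
#' @param smooth_window lateral smoothing window in um.
#' @param rise_frac fraction of the robust maximum defining "signal".
#' @param sustain number of consecutive supra-threshold voxels required.
#' @return matrix `(ny x nx)` of surface depths in um (depth of the top edge
#'   of the first signal voxel).
#' @export
detect_surface <- function(v, smooth_window = 50, rise_frac = 0.1,
                           sustain = 3L) {
  validate_volume(v)
  s <- v$low + v$high
  if (max(s) <= 0) stop_rv("cannot detect a surface in an all-zero volume")
  d <- dim(s)
  thr <- rise_frac * stats::quantile(s[s > 0], 0.99, names = FALSE)
  dz <- v$spacing[1]
  sustain <- min(sustain, d[1])
  depth <- matrix(NA_real_, d[2], d[3])
  for (x in seq_len(d[3])) {
    cols <- s[, , x] >= thr              # nz x ny logical
    for (y in seq_len(d[2])) {
      runs <- rle(cols[, y])
      ends <- cumsum(runs$lengths)
      k <- which(runs$values & runs$lengths >= sustain)
      if (length(k)) {
        z1 <- ends[k[1]] - runs$lengths[k[1]] + 1L
        depth[y, x] <- (z1 - 1L) * dz
      }
    }
  }
  if (all(is.na(depth))) stop_rv("no sustained signal rise found in any column")
  if (anyNA(depth)) depth[is.na(depth)] <- stats::median(depth, na.rm = TRUE)
  w <- max(1L, 2L * floor(smooth_window / (2 * v$spacing[2])) + 1L)
  median_filter2d(depth, w)
}

#' Segment the dermis band below the detected surface
#'
#' The dermis (DE) band is taken as a fixed-thickness slab starting
#' `epidermis_um` below the detected surface and extending `de_depth_um`
#' further down, per column, clipped to the volume with a warning. Depth is
#' measured along z only (surface tilt at mesoscopy scale is small).
#'
#' @param v a [dual_band_volume()].
#' @param surface surface depth map from [detect_surface()].
#' @param epidermis_um epidermis band thickness, um.
#' @param de_depth_um dermis band depth, um.
#' @return an object of class `skin_mask`: list with `surface` (um map),
#'   `de_mask` (logical array), `vessel_mask` (`NULL` until
#'   [segment_vessels()] is run) and `spacing`.
#' @export
segment_dermis <- function(v, surface, epidermis_um = 100,
                           de_depth_um = 500) {
  validate_volume(v)
  d <- dim(v$low)
  if (!identical(dim(surface), d[2:3]))
    stop_rv("surface map shape does not match the volume's lateral grid")
  dz <- v$spacing[1]
  zc <- (seq_len(d[1]) - 0.5) * dz       # voxel-centre depths
  de <- array(FALSE, d)
  clipped <- FALSE
  for (x in seq_len(d[3]))
    for (y in seq_len(d[2])) {
      top <- surface[y, x] + epidermis_um
      bot <- top + de_depth_um
      if (bot > d[1] * dz) clipped <- TRUE
      de[, y, x] <- zc > top & zc <= bot
    }
  if (clipped)
    warn_rv("dermis band exceeds the volume depth; mask clipped")
  structure(list(surface = surface, de_mask = de, vessel_mask = NULL,
                 spacing = v$spacing),
            class = "skin_mask")
}

#' Segment vessel voxels inside the dermis band
#'
#' Thresholds each band separately inside the DE mask (`otsu_band`: Otsu's
#' method on the within-mask intensities; `fixed_percentile`: a fixed
#' quantile of the within-mask intensities), takes the union of the two band
#' masks, and removes connected components (26-connectivity) smaller than
#' `min_size` voxels. Both methods are relative to the intensity
#' distribution, so the segmentation is invariant to global positive
#' intensity scaling.
#'
#' @param v a [dual_band_volume()].
#' @param mask a `skin_mask` from [segment_dermis()].
#' @param method `"otsu_band"` or `"fixed_percentile"`.
#' @param min_size minimum component size in voxels.
#' @param percentile quantile for `fixed_percentile`.
#' @return the `skin_mask` with `vessel_mask` filled (always a subset of
#'   `de_mask`).
#' @export
segment_vessels <- function(v, mask, method = c("otsu_band",
                                                "fixed_percentile"),
                            min_size = 27L, percentile = 0.95) {
  validate_volume(v)
  method <- match.arg(method)
  de <- mask$de_mask
  if (!any(de)) stop_rv("empty dermis mask")
  band_mask <- function(band) {
    vals <- band[de]
    thr <- if (method == "otsu_band") otsu_threshold(vals)
           else stats::quantile(vals, percentile, names = FALSE)
    band > thr & de
  }
  vm <- band_mask(v$low) | band_mask(v$high)
  if (any(vm) && min_size > 1L) {
    lab <- cpp_label3d(vm, dim(vm))
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= min_size)
    vm <- array(lab %in% keep & vm, dim(vm))
  }
  mask$vessel_mask <- vm
  mask
}
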