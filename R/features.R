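#' Per-branch geometry table
#'
#' Computes, for every branch of a [skeletonize_graph()] result: path length
#' (sum of consecutive point distances, after light moving-average smoothing
#' of the voxel chain to suppress digitization staircase bias), tortuosity
#' (path length / Euclidean end-to-end distance; branches with coincident
#' ends are excluded with `NA` and counted separately), diameter (twice the
#' mean per-point radius) and volume (sum of truncated-cone segment volumes
#' `pi * r_mid^2 * segment length`).
#'
#' @param g a `vessel_graph`.
#' @param smooth_pts odd moving-average window (in points) applied to the
#'   chain before measuring length; 1 disables smoothing.
#' @return data frame with one row per branch: `branch`, `type`,
#'   `length_um`, `tortuosity`, `diameter_um`, `volume_um3`.
#' @export
branch_metrics <- function(g, smooth_pts = 9L) {
  if (length(g$branches) == 0L)
    return(data.frame(branch = integer(), type = character(),
                      length_um = double(), tortuosity = double(),
                      diameter_um = double(), volume_um3 = double()))
  rows <- lapply(seq_along(g$branches), function(i) {
    b <- g$branches[[i]]
    pts <- smooth_chain(b$points, smooth_pts)
    seg <- if (nrow(pts) > 1L) sqrt(rowSums(diff(pts)^2)) else numeric(0)
    len <- sum(seg)
    chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    tort <- if (chord > 1e-9) len / chord else NA_real_
    r <- b$radius
    vol <- if (length(seg))
      sum(pi * ((r[-length(r)] + r[-1]) / 2)^2 * seg) else 0
    data.frame(branch = i, type = b$type, length_um = len, tortuosity = tort,
               diameter_um = 2 * mean(r), volume_um3 = vol)
  })
  do.call(rbind, rows)
}

# centred Gaussian-weighted smoothing of an ordered point chain, endpoints
# fixed; suppresses voxel staircase noise with little curvature shrinkage
smooth_chain <- function(pts, w) {
  n <- nrow(pts)
  if (w <= 1L || n <= 2L) return(pts)
  r <- w %/% 2L
  wt <- stats::dnorm(-r:r, sd = r / 2)
  out <- pts
  for (i in 2:(n - 1L)) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    ww <- wt[(lo - i + r + 1L):(hi - i + r + 1L)]
    out[i, ] <- colSums(pts[lo:hi, , drop = FALSE] * ww) / sum(ww)
  }
  out
}

#' Mean inter-branch angle per junction
#'
#' For every junction node, each incident branch contributes a unit tangent
#' estimated from its first `k` skeleton points leaving the node (direction
#' from the node to the mean of those points); the junction's value is the
#' mean angle over all unordered branch pairs, in degrees.
#'
#' @param g a `vessel_graph`.
#' @param k tangent estimation window in skeleton points.
#' @return data frame `node, angle_deg` (one row per junction); zero rows if
#'   the graph has no junctions.
#' @export
junction_angles <- function(g, k = 3L) {
  junc <- g$nodes$id[g$nodes$kind == "junction"]
  if (length(junc) == 0L)
    return(data.frame(node = integer(), angle_deg = double()))
  rows <- lapply(junc, function(j) {
    tangents <- list()
    for (b in g$branches) {
      if (b$from != j && b$to != j) next
      pts <- b$points
      if (b$to == j && b$from != j)
        pts <- pts[nrow(pts):1, , drop = FALSE]
      if (nrow(pts) < 2L) next
      idx <- 2:min(nrow(pts), k + 1L)
      tgt <- colMeans(pts[idx, , drop = FALSE]) - pts[1, ]
      n <- sqrt(sum(tgt^2))
      if (n < 1e-9) next
      tangents[[length(tangents) + 1L]] <- tgt / n
      if (b$from == j && b$to == j) {      # self-loop: second tangent
        pts2 <- pts[nrow(pts):1, , drop = FALSE]
        tgt2 <- colMeans(pts2[idx, , drop = FALSE]) - pts2[1, ]
        n2 <- sqrt(sum(tgt2^2))
        if (n2 > 1e-9)
          tangents[[length(tangents) + 1L]] <- tgt2 / n2
      }
    }
    if (length(tangents) < 2L)
      return(data.frame(node = j, angle_deg = NA_real_))
    pairs <- utils::combn(length(tangents), 2L)
    ang <- apply(pairs, 2L, function(p) {
      cosv <- sum(tangents[[p[1]]] * tangents[[p[2]]])
      acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
    })
    data.frame(node = j, angle_deg = mean(ang))
  })
  do.call(rbind, rows)
}

#' Extract the 18 dermal features from a segmented volume
#'
#' Combines the dual-band volume, the skin mask (dermis band + vessel
#' voxels) and the skeleton graph into the canonical 18-feature vector (see
#' [feature_names()] for order, [feature_units()] for units,
#' [feature_scales()] for the micro/meso/macro labels). Mean-type features
#' of an empty graph are `NA` (a percentage change of an undefined mean is
#' undefined); count features are 0.
#'
#' Definitions: f1 mean junction angle; f2-f6 means over branches of length,
#' tortuosity, length/diameter, diameter, volume; f7 branch count; f8
#' junctions per dermis volume (mm^-3); f9 vessel-voxel fraction of the
#' dermis; f10 junctions/vessels; f11-f13 J2J, J2E and junction counts; f14
#' mean per-column dermis thickness (um); f15 en-face (depth-projection)
#' vessel area (mm^2); f16/f17 mean summed-band intensity over vessel/dermis
#' voxels; f18 side-projection (z, x) dermis area (mm^2).
#'
#' @param v a [dual_band_volume()].
#' @param m a `skin_mask` with `vessel_mask` filled.
#' @param g a `vessel_graph`.
#' @return named numeric vector of length 18 with attributes `scales` and
#'   `units`, class `feature_vector`.
#' @export
extract_features <- function(v, m, g) {
  validate_volume(v)
  if (is.null(m$vessel_mask)) stop_rv("run segment_vessels() first")
  sp <- v$spacing
  bm <- branch_metrics(g)
  ja <- junction_angles(g)
  n_branches <- nrow(bm)
  n_junc <- sum(g$nodes$kind == "junction")
  n_j2j <- sum(bm$type == "J2J")
  n_j2e <- sum(bm$type == "J2E")

  de_vox <- sum(m$de_mask)
  de_vol_mm3 <- de_vox * prod(sp) / 1e9
  ves_vox <- sum(m$vessel_mask)
  ssum <- v$low + v$high

  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else
    mean(x, na.rm = TRUE)

  f <- c(
    avg_junction_angle = if (nrow(ja)) mean(ja$angle_deg, na.rm = TRUE)
                         else NA_real_,
    avg_vessel_length = mean_or_na(bm$length_um),
    avg_tortuosity = mean_or_na(bm$tortuosity),
    length_to_width_ratio = mean_or_na(bm$length_um / bm$diameter_um),
    avg_vessel_diameter = mean_or_na(bm$diameter_um),
    avg_vessel_volume = mean_or_na(bm$volume_um3),
    num_vessels = n_branches,
    junction_density = if (de_vol_mm3 > 0) n_junc / de_vol_mm3 else NA_real_,
    vascular_density = if (de_vox > 0) ves_vox / de_vox else NA_real_,
    junctions_to_vessels_ratio = if (n_branches > 0) n_junc / n_branches
                                 else 0,
    num_j2j_branches = n_j2j,
    num_j2e_branches = n_j2e,
    num_junctions = n_junc,
    de_thickness = mean(apply(m$de_mask, c(2, 3), sum)) * sp[1],
    total_vessel_area = sum(apply(m$vessel_mask, c(2, 3), any)) *
      sp[2] * sp[3] / 1e6,
    mean_signal_vessels = if (ves_vox > 0) mean(ssum[m$vessel_mask])
                          else NA_real_,
    mean_signal_de = if (de_vox > 0) mean(ssum[m$de_mask]) else NA_real_,
    de_area = sum(apply(m$de_mask, c(1, 3), any)) * sp[1] * sp[3] / 1e6
  )
  structure(f, scales = feature_scales(), units = feature_units(),
            class = "feature_vector")
}

#' Full single-volume pipeline: volume to feature vector
#'
#' Convenience wrapper running [detect_surface()], [segment_dermis()],
#' [segment_vessels()], [skeletonize_graph()] and [extract_features()] with
#' their defaults.
#'
#' @param v a [dual_band_volume()].
#' @param epidermis_um,de_depth_um dermis band geometry, um.
#' @param prune_um spur-pruning threshold, um.
#' @param ... passed to [segment_vessels()].
#' @return list with `features`, `mask`, `graph`.
#' @export
analyze_volume <- function(v, epidermis_um = 100, de_depth_um = 500,
                           prune_um = 50, ...) {
  surf <- detect_surface(v)
  m <- segment_dermis(v, surf, epidermis_um, de_depth_um)
  m <- segment_vessels(v, m, ...)
  g <- skeletonize_graph(m$vessel_mask, v$spacing, prune_um = prune_um)
  list(features = extract_features(v, m, g), mask = m, graph = g)
}
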