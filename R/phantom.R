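#' Synthetic dermal vessel tree
#'
#' Grows a ground-truthed tubular vessel network inside a dermis band by a
#' stochastic branching random walk with radius taper. Walkers start at
#' random seeds in the dermis, take fixed-length steps with direction
#' jitter, are reflected at the dermis boundaries, and split into two
#' daughter branches with a per-step branching probability. A collision
#' guard terminates walkers that approach an unrelated branch, so distinct
#' branches never merge and the stored topology is the exact ground truth
#' for the skeleton stage.
#'
#' @param n_seeds number of independent root walkers.
#' @param branching_prob per-step probability of a bifurcation (after
#'   `min_steps`).
#' @param radius_range interval (um) for the root radius draw; must lie in
#'   `(0, dermis thickness / 2)`.
#' @param domain volume extents `(z, y, x)` in um.
#' @param dermis `(z_top, z_bottom)` of the dermis band in um.
#' @param epidermis_um epidermis slab thickness above the dermis, um.
#' @param step_um walker step length, um.
#' @param max_steps,min_steps per-branch step budget and the minimum number
#'   of steps before a branch may bifurcate or be counted.
#' @param taper multiplicative per-step radius taper.
#' @param child_factor daughter-to-parent radius ratio at a bifurcation.
#' @param split_angle half-angle (degrees) between daughters at a bifurcation.
#' @param jitter direction jitter scale per step.
#' @param avoid_um extra clearance (um) enforced between unrelated branches.
#' @param min_branch_um terminal branches shorter than this are discarded
#'   (a walker blocked early by the collision guard would otherwise leave a
#'   stub below the skeleton stage's spur-pruning scale).
#' @param max_branches hard cap on the number of branches.
#' @param seed integer seed; the generator is fully reproducible.
#' @return An object of class `vessel_tree`: list with `branches` (each a
#'   list with `points` n x 3 matrix in um, `radius` per point, `from`, `to`
#'   node ids), `nodes` (data frame `id, z, y, x, kind`), `dermis`,
#'   `epidermis_um`, `domain` and `ground_truth` (see [tree_ground_truth()]).
#' @export
generate_vessel_tree <- function(n_seeds = 4, branching_prob = 0.3,
                                 radius_range = c(15, 40),
                                 domain = c(600, 400, 400),
                                 dermis = c(150, 550), epidermis_um = 100,
                                 step_um = 15, max_steps = 40, min_steps = 8,
                                 taper = 0.997, child_factor = 0.85,
                                 split_angle = 55, jitter = 0.25,
                                 avoid_um = 45, min_branch_um = 100,
                                 max_branches = 200, seed = 1) {
  th <- dermis[2] - dermis[1]
  if (radius_range[1] <= 0 || radius_range[2] >= th / 2)
    stop_rv("radius_range must lie in (0, dermis thickness/2) = (0, %g)", th / 2)
  if (any(domain[2:3] < 6 * radius_range[2]))
    stop_rv("lateral domain too small for radius_range (need >= %g um)",
            6 * radius_range[2])
  set.seed(child_seed(seed, "tree"))

  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  perp_unit <- function(d) {
    v <- stats::rnorm(3)
    v <- v - sum(v * d) * d
    n <- sqrt(sum(v^2))
    if (n < 1e-9) return(perp_unit(d))
    v / n
  }

  branches <- list()
  nodes <- data.frame(id = integer(), z = double(), y = double(),
                      x = double())
  add_node <- function(p) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- c(id, p)
    id
  }
  # pooled occupied points for the collision guard:
  # (z, y, x, radius, branch, step)
  occ <- matrix(numeric(0), ncol = 6)

  lat_lo <- radius_range[2] + 5
  margin <- function(r) c(dermis[1] + r + 5, dermis[2] - r - 5)

  # walker queue: each entry pos, dir, radius, from-node, parent branch id
  queue <- list()
  for (i in seq_len(n_seeds)) {
    r0 <- stats::runif(1, radius_range[1], radius_range[2])
    zb <- margin(r0)
    pos <- NULL
    for (try in 1:50) {                      # keep roots clear of each other
      cand <- c(stats::runif(1, zb[1], zb[2]),
                stats::runif(1, lat_lo, domain[2] - lat_lo),
                stats::runif(1, lat_lo, domain[3] - lat_lo))
      clear <- nrow(occ) == 0L ||
        all((occ[, 1] - cand[1])^2 + (occ[, 2] - cand[2])^2 +
              (occ[, 3] - cand[3])^2 >=
              (occ[, 4] + r0 + avoid_um + 4 * step_um)^2)
      if (clear) { pos <- cand; break }
    }
    if (is.null(pos)) next
    d <- rand_unit()
    d[1] <- d[1] * 0.3                       # mostly lateral plexus
    d <- d / sqrt(sum(d^2))
    queue[[length(queue) + 1L]] <- list(pos = pos, dir = d, r = r0,
                                        from = add_node(pos), parent = NA)
    occ <- rbind(occ, c(pos, r0, 0, 0))      # reserve the root sphere
  }

  too_close <- function(p, r, own, step, start) {
    if (nrow(occ) == 0L) return(FALSE)
    d2 <- (occ[, 1] - p[1])^2 + (occ[, 2] - p[2])^2 + (occ[, 3] - p[3])^2
    lim <- (occ[, 4] + r + avoid_um)^2
    hit <- d2 < lim
    if (!any(hit)) return(FALSE)
    # exempt the walker's own recent trail (but not older self-points, so a
    # looping walker is stopped) and anything near the shared junction
    # (parent and sibling points within a few steps of the walker's start)
    ok <- (occ[hit, 5] == own & occ[hit, 6] > step - 8) |
      ((occ[hit, 1] - start[1])^2 + (occ[hit, 2] - start[2])^2 +
         (occ[hit, 3] - start[3])^2) < (4 * step_um)^2
    any(!ok)
  }

  while (length(queue) > 0L && length(branches) < max_branches) {
    w <- queue[[1L]]
    queue[[1L]] <- NULL
    bid <- length(branches) + 1L
    pts <- matrix(w$pos, ncol = 3)
    rad <- w$r
    d <- w$dir
    r <- w$r
    end_node <- NA_integer_
    spawned <- FALSE
    for (s in seq_len(max_steps)) {
      d <- d + jitter * stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      p <- pts[nrow(pts), ] + step_um * d
      zb <- margin(r)
      if (p[1] < zb[1] || p[1] > zb[2]) { d[1] <- -d[1]; p[1] <- pmin(pmax(p[1], zb[1]), zb[2]) }
      if (p[2] < lat_lo || p[2] > domain[2] - lat_lo) { d[2] <- -d[2]; p[2] <- pmin(pmax(p[2], lat_lo), domain[2] - lat_lo) }
      if (p[3] < lat_lo || p[3] > domain[3] - lat_lo) { d[3] <- -d[3]; p[3] <- pmin(pmax(p[3], lat_lo), domain[3] - lat_lo) }
      if (too_close(p, r, bid, s, pts[1, ])) break
      pts <- rbind(pts, p)
      rad <- c(rad, r)
      occ <- rbind(occ, c(p, r, bid, s))
      r <- max(r * taper, radius_range[1])
      if (s >= min_steps && length(branches) + length(queue) < max_branches &&
          stats::runif(1) < branching_prob) {
        end_node <- add_node(p)
        u <- perp_unit(d)
        a <- (split_angle + stats::rnorm(1, 0, 5)) * pi / 180
        for (sgn in c(1, -1)) {
          dd <- cos(a) * d + sgn * sin(a) * u
          queue[[length(queue) + 1L]] <-
            list(pos = p, dir = dd / sqrt(sum(dd^2)),
                 r = max(r * child_factor, radius_range[1]),
                 from = end_node, parent = c(w$parent, bid))
        }
        spawned <- TRUE
        break
      }
    }
    if (nrow(pts) < 2L) next               # walker blocked at its first step
    # terminal stubs below the spur-pruning scale are discarded; the bound
    # accounts for skeleton end-retraction of about one radius at each end
    if (!spawned &&
        sum(sqrt(rowSums(diff(pts)^2))) <
          min_branch_um + rad[1] + rad[length(rad)]) next
    if (!spawned) end_node <- add_node(pts[nrow(pts), ])
    branches[[bid]] <- list(points = unname(pts), radius = unname(rad),
                            from = w$from, to = end_node)
  }

  tree <- structure(list(branches = branches, nodes = nodes,
                         dermis = dermis, epidermis_um = epidermis_um,
                         domain = domain,
                         params = list(seed = seed, step_um = step_um)),
                    class = "vessel_tree")
  tree$ground_truth <- tree_ground_truth(tree)
  tree
}

#' Ground-truth morphometry of a stored vessel tree
#'
#' Recomputes topology counts and per-branch geometry directly from the
#' stored branch/node structure (independently of any rasterization or
#' skeletonization). Degree-2 nodes (a bifurcation whose second daughter was
#' blocked by the collision guard) are dissolved — the two incident branches
#' are merged into one — so the reported counts describe the same graph a
#' topology-preserving skeletonization sees: node degrees, branch types
#' (junction-to-junction, junction-to-endpoint, endpoint-to-endpoint),
#' lengths, tortuosities and mean radii.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @return list with `n_branches`, `n_junctions`, `n_endpoints`, `n_j2j`,
#'   `n_j2e`, `n_e2e`, and a per-branch data frame `branch_table`
#'   (`length_um`, `tortuosity`, `mean_radius_um`, `type`).
#' @export
tree_ground_truth <- function(tree) {
  g <- structure(list(branches = tree$branches, spacing = c(1, 1, 1)),
                 class = "vessel_graph")
  g <- dissolve_degree2(g)
  branches <- g$branches
  n <- max(c(0L, vapply(branches, function(b) max(b$from, b$to), 0L)))
  deg <- integer(n)
  for (b in branches) {
    deg[b$from] <- deg[b$from] + 1L
    deg[b$to] <- deg[b$to] + 1L
  }
  kind <- ifelse(deg >= 3L, "junction", "endpoint")
  bt <- do.call(rbind, lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    len <- if (nrow(b$points) < 2L) 0 else
      sum(sqrt(rowSums(diff(b$points)^2)))
    chord <- sqrt(sum((b$points[nrow(b$points), ] - b$points[1, ])^2))
    ends <- sort(c(kind[b$from], kind[b$to]))
    type <- if (identical(ends, c("junction", "junction"))) "J2J"
            else if (identical(ends, c("endpoint", "junction"))) "J2E"
            else "E2E"
    data.frame(branch = i, length_um = len,
               tortuosity = if (chord > 0) len / chord else NA_real_,
               mean_radius_um = mean(b$radius), type = type)
  }))
  list(n_branches = length(branches),
       n_junctions = sum(kind == "junction" & deg > 0),
       n_endpoints = sum(kind == "endpoint" & deg > 0),
       n_j2j = sum(bt$type == "J2J"),
       n_j2e = sum(bt$type == "J2E"),
       n_e2e = sum(bt$type == "E2E"),
       branch_table = bt,
       node_degree = deg)
}

# resample a branch centerline at arc steps <= `step` um and return capsule
# segments (z1, y1, x1, r1, z2, y2, x2, r2), one row per consecutive pair
branch_segments <- function(points, radius, step) {
  if (nrow(points) == 1L) {
    p <- c(points[1, ], radius[1])
    return(matrix(c(p, p, 1, 1), nrow = 1))
  }
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  t <- unique(c(seq(0, L, by = step), L))
  dense <- cbind(stats::approx(s, points[, 1], t)$y,
                 stats::approx(s, points[, 2], t)$y,
                 stats::approx(s, points[, 3], t)$y,
                 stats::approx(s, radius, t)$y)
  n <- nrow(dense)
  m <- n - 1L
  # every joint and both ends are capped: tubes are capsule chains with
  # rounded ends (flat-ended tubes lose one radius of skeleton at each tip,
  # rounded ends compensate the thinning retraction almost exactly)
  cbind(dense[-n, , drop = FALSE], dense[-1, , drop = FALSE],
        cap1 = rep(1, m), cap2 = rep(1, m))
}

#' Rasterize a vessel tree into a dual-band volume
#'
#' Stamps every branch as a tube of its local radius into a voxel grid.
#' Branches whose mean radius is at least `band_threshold_um` are written to
#' the low-frequency band (larger microvessels), the rest to the
#' high-frequency band. This single-threshold assignment emulates the
#' acoustic frequency split geometrically; the split in a real device is
#' acoustic, not geometric. An epidermis slab of high intensity is written
#' above the dermis in both bands, and optional Gaussian noise (clipped at 0)
#' is added everywhere.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param spacing isotropic voxel spacing in um (or length-3 `(dz, dy, dx)`).
#' @param band_threshold_um radius threshold separating the bands, um.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param radius_scale multiplicative factor applied to every radius (used by
#'   the reactivity phases).
#' @param active integer vector of branch ids to rasterize (default all).
#' @param intensity tube intensity (a.u.).
#' @param epidermis_intensity intensity of the epidermis slab.
#' @param seed seed for the noise draw.
#' @return a [dual_band_volume()] with attribute `ground_truth`: list of
#'   logical arrays `vessel_mask`, `low_mask`, `high_mask` (noise-free tube
#'   voxels).
#' @export
rasterize_tree <- function(tree, spacing = 10, band_threshold_um = 30,
                           noise_sd = 0, radius_scale = 1, active = NULL,
                           intensity = 1, epidermis_intensity = 1, seed = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dims <- as.integer(ceiling(tree$domain / spacing))
  active <- active %||% seq_along(tree$branches)
  low <- array(FALSE, dims)
  high <- array(FALSE, dims)
  step <- min(spacing)
  for (i in active) {
    b <- tree$branches[[i]]
    segs <- branch_segments(b$points, b$radius * radius_scale, step)
    target <- if (mean(b$radius * radius_scale) >= band_threshold_um)
      "low" else "high"
    if (target == "low")
      low <- cpp_stamp_tubes(segs, dims, spacing, low)
    else
      high <- cpp_stamp_tubes(segs, dims, spacing, high)
  }
  dim(low) <- dims; dim(high) <- dims
  zc <- (seq_len(dims[1]) - 0.5) * spacing[1]
  epi <- zc >= (tree$dermis[1] - tree$epidermis_um) & zc < tree$dermis[1]
  low_arr <- intensity * low
  high_arr <- intensity * high
  low_arr[epi, , ] <- pmax(low_arr[epi, , ], epidermis_intensity)
  high_arr[epi, , ] <- pmax(high_arr[epi, , ], epidermis_intensity)
  if (noise_sd > 0) {
    set.seed(child_seed(seed, "noise"))
    low_arr <- pmax(low_arr + array(stats::rnorm(prod(dims), 0, noise_sd), dims), 0)
    high_arr <- pmax(high_arr + array(stats::rnorm(prod(dims), 0, noise_sd), dims), 0)
  }
  v <- dual_band_volume(low_arr, high_arr, spacing)
  attr(v, "ground_truth") <- list(vessel_mask = low | high,
                                  low_mask = low, high_mask = high)
  v
}

#' Group-dependent PORH reactivity model
#'
#' Per-phase multiplicative factors encoding the generator's hyperemic
#' response: radii are unchanged at baseline, mildly reduced during
#' occlusion, and dilated after cuff release, with the healthy dilation
#' exceeding the patient dilation (the blunted-response effect). A reserve
#' subset of branches is invisible at baseline and recruited at hyperemia
#' with group-dependent probability.
#'
#' @param radius_factor 2 x 6 matrix (rows `healthy`, `patient`; columns
#'   [porh_timepoints()]) of radius factors.
#' @param recruit_p 2 x 6 matrix of per-branch recruitment probabilities for
#'   the reserve subset.
#' @param recruit_frac fraction of branches held in reserve.
#' @param intensity_factor 2 x 6 matrix of signal intensity factors.
#' @param noise_sd rasterization noise level.
#' @return list of class `reactivity_model`.
#' @export
reactivity_model <- function(radius_factor = NULL, recruit_p = NULL,
                             recruit_frac = 0.25, intensity_factor = NULL,
                             noise_sd = 0) {
  tp <- porh_timepoints()
  mk <- function(h, p) {
    m <- rbind(healthy = h, patient = p)
    colnames(m) <- tp
    m
  }
  radius_factor <- radius_factor %||%
    mk(c(1, 1, 0.9, 0.9, 1.30, 1.15), c(1, 1, 0.9, 0.9, 1.10, 1.05))
  recruit_p <- recruit_p %||%
    mk(c(0, 0, 0, 0, 0.9, 0.7), c(0, 0, 0, 0, 0.3, 0.2))
  intensity_factor <- intensity_factor %||% mk(rep(1, 6), rep(1, 6))
  label <- function(m) {
    if (is.null(colnames(m))) colnames(m) <- tp
    if (is.null(rownames(m))) rownames(m) <- c("healthy", "patient")
    m
  }
  radius_factor <- label(radius_factor)
  recruit_p <- label(recruit_p)
  intensity_factor <- label(intensity_factor)
  if (any(radius_factor[, "baseline"] != 1))
    stop_rv("baseline radius factors must be 1")
  if (any(radius_factor[, c("occl1", "occl2", "occl3")] > 1))
    stop_rv("occlusion radius factors must be <= 1")
  if (radius_factor["healthy", "hyp1"] <= radius_factor["patient", "hyp1"])
    stop_rv("healthy hyperemia radius factor must exceed the patient factor")
  structure(list(radius_factor = radius_factor, recruit_p = recruit_p,
                 recruit_frac = recruit_frac,
                 intensity_factor = intensity_factor, noise_sd = noise_sd),
            class = "reactivity_model")
}

#' Generate a six-volume PORH series from a phantom tree
#'
#' Applies a [reactivity_model()] to a vessel tree and rasterizes one volume
#' per protocol timepoint. The baseline volume is the unscaled tree minus the
#' reserve subset; later phases scale every radius by the group's per-phase
#' factor and recruit reserve branches with the group's per-phase
#' probability. The imposed ground-truth percentage changes are returned
#' alongside the volumes.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param model a [reactivity_model()].
#' @param group `"healthy"` or `"patient"`.
#' @param spacing voxel spacing, um.
#' @param band_threshold_um band-assignment radius threshold, um.
#' @param seed integer seed (reserve draw, recruitment, noise).
#' @return list with `volumes` (named list of six [dual_band_volume()]s),
#'   `ground_truth` (data frame per timepoint: `radius_factor`,
#'   `delta_diameter_pct`, `n_active`, `delta_num_vessels_pct`), `group` and
#'   `reserve` (branch ids held in reserve).
#' @export
generate_porh_series <- function(tree, model = reactivity_model(),
                                 group = c("healthy", "patient"),
                                 spacing = 10, band_threshold_um = 30,
                                 seed = 1) {
  group <- match.arg(group)
  tp <- porh_timepoints()
  n <- length(tree$branches)
  set.seed(child_seed(seed, "reserve"))
  n_res <- round(model$recruit_frac * n)
  reserve <- if (n_res > 0) sort(sample.int(n, n_res)) else integer(0)
  base_active <- setdiff(seq_len(n), reserve)
  volumes <- list()
  gt <- data.frame(timepoint = tp, radius_factor = NA_real_,
                   delta_diameter_pct = NA_real_, n_active = NA_integer_,
                   delta_num_vessels_pct = NA_real_)
  for (j in seq_along(tp)) {
    f <- model$radius_factor[group, j]
    set.seed(child_seed(seed, paste0("recruit-", j)))
    rec <- reserve[stats::runif(length(reserve)) < model$recruit_p[group, j]]
    act <- sort(c(base_active, rec))
    volumes[[tp[j]]] <- rasterize_tree(
      tree, spacing = spacing, band_threshold_um = band_threshold_um,
      noise_sd = model$noise_sd, radius_scale = f, active = act,
      intensity = model$intensity_factor[group, j],
      seed = child_seed(seed, paste0("vol-", j)))
    gt$radius_factor[j] <- f
    gt$delta_diameter_pct[j] <- 100 * (f - 1)
    gt$n_active[j] <- length(act)
  }
  gt$delta_num_vessels_pct <- 100 * (gt$n_active - gt$n_active[1]) / gt$n_active[1]
  list(volumes = volumes, ground_truth = gt, group = group, reserve = reserve)
}
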