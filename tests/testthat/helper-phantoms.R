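# shared phantom builders: hand-specified trees with known geometry.
# Centrelines are placed at voxel centres (coordinates at odd multiples of
# half the spacing) so cross-sections are odd-width; a tube centred exactly
# on a voxel corner has no unique medial line and degrades any homotopic
# thinning, including the reference implementations.

manual_tree <- function(branches, domain = c(600, 400, 400),
                        dermis = c(150, 550), epidermis_um = 100) {
  n <- max(unlist(lapply(branches, function(b) c(b$from, b$to))))
  tr <- list(branches = branches, nodes = data.frame(id = seq_len(n)),
             dermis = dermis, epidermis_um = epidermis_um, domain = domain)
  class(tr) <- "vessel_tree"
  tr
}

straight_tube_tree <- function(r = 30, z = 295, y = 195,
                               x0 = 55, x1 = 345) {
  manual_tree(list(list(points = rbind(c(z, y, x0), c(z, y, x1)),
                        radius = c(r, r), from = 1L, to = 2L)))
}

y_tree <- function(r = 22, ctr = c(295, 195, 195), L = 140) {
  arm <- function(ang, to) {
    d <- c(0, sin(ang), cos(ang))
    list(points = rbind(ctr, ctr + L * d), radius = c(r, r),
         from = 1L, to = to)
  }
  manual_tree(list(arm(0, 2L), arm(2 * pi / 3, 3L), arm(-2 * pi / 3, 4L)))
}

semicircle_tree <- function(r_arc = 120, r_tube = 20) {
  th <- seq(0, pi, length.out = 60)
  pts <- cbind(295, 195 + r_arc * sin(th), 195 - r_arc * cos(th))
  manual_tree(list(list(points = pts, radius = rep(r_tube, 60),
                        from = 1L, to = 2L)))
}

helix_tree <- function(r_helix = 100, pitch = 200, turns = 2, r_tube = 18) {
  t <- seq(0, turns * 2 * pi, length.out = 100 * turns)
  pts <- cbind(205 + pitch * t / (2 * pi),
               195 + r_helix * sin(t), 195 + r_helix * cos(t))
  manual_tree(list(list(points = pts, radius = rep(r_tube, length(t)),
                        from = 1L, to = 2L)))
}

# volume -> (mask, graph) with the defaults used throughout the tests
run_pipeline <- function(v, de_depth_um = 400) {
  m <- segment_dermis(v, detect_surface(v), 100, de_depth_um)
  m <- segment_vessels(v, m)
  g <- skeletonize_graph(m$vessel_mask, v$spacing)
  list(m = m, g = g)
}

# small two-band volume with distinct values for IO tests
toy_volume <- function(nz = 16, ny = 16, nx = 16, seed = 1) {
  set.seed(seed)
  low <- array(sample(0:4000, nz * ny * nx, replace = TRUE), c(nz, ny, nx))
  high <- array(sample(0:4000, nz * ny * nx, replace = TRUE), c(nz, ny, nx))
  dual_band_volume(low, high, c(10, 10, 10))
}
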