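test_that("a straight tube reduces to one straight branch", {
  v <- rasterize_tree(straight_tube_tree(), spacing = 10)
  p <- run_pipeline(v)
  expect_equal(length(p$g$branches), 1)
  expect_equal(sum(p$g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(p$g$nodes$kind == "junction"), 0)
  bm <- branch_metrics(p$g)
  expect_equal(bm$tortuosity, 1, tolerance = 0.01)
  expect_equal(bm$diameter_um, 60, tolerance = 0.15 * 60)
  expect_equal(bm$length_um, 290, tolerance = 0.1 * 290)
})

test_that("a symmetric Y yields one junction, three J2E branches, 120 degrees", {
  v <- rasterize_tree(y_tree(), spacing = 10)
  p <- run_pipeline(v)
  expect_equal(sum(p$g$nodes$kind == "junction"), 1)
  bm <- branch_metrics(p$g)
  expect_equal(nrow(bm), 3)
  expect_true(all(bm$type == "J2E"))
  ja <- junction_angles(p$g)
  expect_equal(ja$angle_deg, 120, tolerance = 3 / 120)
})

test_that("junction angles on a hand-built graph follow plane geometry", {
  # straight-through node with an orthogonal side branch: 90 + 90 + 180
  mk_branch <- function(to, d, n = 10) {
    pts <- t(vapply(0:n, function(i) c(0, 0, 0) + i * 10 * d, double(3)))
    list(points = pts, radius = rep(5, n + 1), from = 1L, to = to,
         type = "J2E")
  }
  g <- structure(list(
    nodes = data.frame(id = 1:4, z = 0, y = 0, x = 0,
                       kind = c("junction", rep("endpoint", 3)),
                       degree = c(3L, 1L, 1L, 1L)),
    branches = list(mk_branch(2L, c(0, 0, 1)),
                    mk_branch(3L, c(0, 0, -1)),
                    mk_branch(4L, c(0, 1, 0))),
    spacing = c(10, 10, 10)), class = "vessel_graph")
  ja <- junction_angles(g)
  expect_equal(ja$angle_deg, mean(c(90, 90, 180)))
})

test_that("curved branches keep their analytic arc length and tortuosity", {
  v <- rasterize_tree(semicircle_tree(), spacing = 10)
  bm <- branch_metrics(run_pipeline(v)$g)
  expect_equal(nrow(bm), 1)
  expect_equal(bm$tortuosity, pi / 2, tolerance = 0.02 / (pi / 2))
  # helix: skeleton length per covered axial span matches the closed form
  # sqrt((2 pi r)^2 + p^2) / p; tube ends retract by about one radius
  v2 <- rasterize_tree(helix_tree(), spacing = 10)
  g2 <- run_pipeline(v2)$g
  expect_equal(length(g2$branches), 1)
  b <- g2$branches[[1]]
  span <- abs(b$points[nrow(b$points), 1] - b$points[1, 1])
  expected <- span * sqrt((2 * pi * 100)^2 + 200^2) / 200
  bm2 <- branch_metrics(g2)
  expect_equal(bm2$length_um, expected, tolerance = 0.02)
})

test_that("branch counts are conserved and recovered on random phantoms", {
  n_exact <- 0
  seeds <- 1:20
  for (seed in seeds) {
    tr <- generate_vessel_tree(n_seeds = 3, branching_prob = 0.25,
                               seed = seed)
    gt <- tr$ground_truth
    v <- rasterize_tree(tr, spacing = 10)
    p <- run_pipeline(v)
    fv <- extract_features(v, p$m, p$g)
    # conservation: total branches = J2J + J2E + E2E, on every graph
    bm <- branch_metrics(p$g)
    expect_equal(fv[["num_vessels"]],
                 fv[["num_j2j_branches"]] + fv[["num_j2e_branches"]] +
                   sum(bm$type == "E2E"))
    exact <- fv[["num_vessels"]] == gt$n_branches &&
      fv[["num_junctions"]] == gt$n_junctions
    n_exact <- n_exact + exact
    expect_equal(mean(bm$diameter_um),
                 2 * mean(gt$branch_table$mean_radius_um),
                 tolerance = 0.15)
  }
  expect_gte(n_exact, ceiling(0.9 * length(seeds)))
})

test_that("features respect their structural invariants on a random phantom", {
  tr <- generate_vessel_tree(n_seeds = 4, branching_prob = 0.35, seed = 17)
  v <- rasterize_tree(tr, spacing = 10)
  p <- run_pipeline(v)
  fv <- extract_features(v, p$m, p$g)
  bm <- branch_metrics(p$g)
  expect_true(all(bm$tortuosity >= 1 - 1e-9, na.rm = TRUE))
  expect_gte(fv[["vascular_density"]], 0)
  expect_lte(fv[["vascular_density"]], 1)
  expect_equal(fv[["junctions_to_vessels_ratio"]],
               fv[["num_junctions"]] / fv[["num_vessels"]])
  expect_equal(fv[["mean_signal_vessels"]], 1, tolerance = 1e-9)
})

test_that("count features are scale-equivariant across voxel spacings", {
  tr <- generate_vessel_tree(n_seeds = 2, branching_prob = 0.25,
                             radius_range = c(30, 40), seed = 5)
  res <- lapply(c(10, 5), function(sp) {
    v <- rasterize_tree(tr, spacing = sp)
    p <- run_pipeline(v)
    extract_features(v, p$m, p$g)
  })
  f10 <- res[[1]]; f5 <- res[[2]]
  for (f in c("num_vessels", "num_junctions", "num_j2j_branches",
              "num_j2e_branches"))
    expect_equal(f10[[f]], f5[[f]])
  for (f in c("avg_vessel_length", "avg_vessel_diameter", "de_thickness"))
    expect_equal(f10[[f]], f5[[f]], tolerance = 0.15)
})

test_that("rotating a phantom 90 degrees about z preserves the features", {
  tr <- generate_vessel_tree(n_seeds = 2, branching_prob = 0.25, seed = 19,
                             domain = c(600, 400, 400))
  rot <- tr
  rot$branches <- lapply(tr$branches, function(b) {
    p <- b$points
    b$points <- cbind(p[, 1], p[, 3], 400 - p[, 2])
    b
  })
  f1 <- local({
    v <- rasterize_tree(tr, spacing = 10); p <- run_pipeline(v)
    extract_features(v, p$m, p$g)
  })
  f2 <- local({
    v <- rasterize_tree(rot, spacing = 10); p <- run_pipeline(v)
    extract_features(v, p$m, p$g)
  })
  for (f in c("num_vessels", "num_junctions", "num_j2j_branches"))
    expect_equal(f1[[f]], f2[[f]])
  for (f in c("avg_vessel_length", "avg_vessel_diameter", "avg_tortuosity",
              "vascular_density", "de_thickness"))
    expect_equal(f1[[f]], f2[[f]], tolerance = 0.1)
})

test_that("an empty mask gives an empty graph and flagged features", {
  g <- skeletonize_graph(array(FALSE, c(10, 10, 10)), 10)
  expect_equal(length(g$branches), 0)
  v <- rasterize_tree(straight_tube_tree(), spacing = 10)
  m <- segment_dermis(v, detect_surface(v), 100, 400)
  m$vessel_mask <- array(FALSE, dim(v$low))
  fv <- extract_features(v, m, g)
  expect_equal(fv[["num_vessels"]], 0)
  expect_equal(fv[["junctions_to_vessels_ratio"]], 0)
  expect_true(is.na(fv[["avg_vessel_diameter"]]))
})
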