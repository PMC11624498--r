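test_that("the surface of a flat phantom is found at the epidermis top", {
  tr <- straight_tube_tree()
  v <- rasterize_tree(tr, spacing = 10)     # epidermis slab at 50-150 um
  surf <- detect_surface(v)
  expect_true(all(abs(surf - 50) <= 10))    # within one voxel
  dark <- dual_band_volume(array(0, c(8, 8, 8)), array(0, c(8, 8, 8)))
  expect_error(detect_surface(dark), "all-zero")
})

test_that("a tilted surface is recovered with its slope", {
  # synthetic slab whose top follows a lateral ramp
  d <- c(60, 30, 30)
  low <- array(0, d)
  slope <- 0.5                              # voxels of depth per column
  for (x in seq_len(d[3])) {
    z0 <- round(10 + slope * x)
    low[z0:(z0 + 8), , x] <- 1
  }
  v <- dual_band_volume(low, low, c(10, 10, 10))
  surf <- detect_surface(v, smooth_window = 10)
  fit <- stats::lm(depth ~ x, data = data.frame(
    depth = as.vector(surf), x = rep(seq_len(d[3]), each = d[2]) * 10))
  expect_lt(abs(coef(fit)["x"] - slope) / slope, 0.1)
})

test_that("the dermis band has the requested thickness and clips with warning", {
  tr <- straight_tube_tree()
  v <- rasterize_tree(tr, spacing = 10)
  m <- segment_dermis(v, detect_surface(v), 100, 400)
  per_col <- apply(m$de_mask, c(2, 3), sum) * 10
  expect_true(all(per_col == 400))
  expect_warning(segment_dermis(v, detect_surface(v), 100, 2000), "clipped")
})

test_that("phantom vessel voxels fall inside the dermis band", {
  tr <- generate_vessel_tree(n_seeds = 3, branching_prob = 0.3, seed = 12)
  v <- rasterize_tree(tr, spacing = 10)
  gt <- attr(v, "ground_truth")
  m <- segment_dermis(v, detect_surface(v), 100, 400)
  expect_gte(sum(gt$vessel_mask & m$de_mask) / sum(gt$vessel_mask), 0.99)
})

test_that("vessel segmentation matches ground truth and stays inside the DE", {
  tr <- generate_vessel_tree(n_seeds = 3, branching_prob = 0.3, seed = 8)
  v <- rasterize_tree(tr, spacing = 10)
  gt <- attr(v, "ground_truth")
  m <- segment_dermis(v, detect_surface(v), 100, 400)
  m <- segment_vessels(v, m)
  dice <- 2 * sum(m$vessel_mask & gt$vessel_mask) /
    (sum(m$vessel_mask) + sum(gt$vessel_mask))
  expect_gte(dice, 0.9)
  expect_true(all(m$de_mask[m$vessel_mask]))      # vessel_mask subset of DE
  # invariant to global positive intensity scaling
  v7 <- dual_band_volume(v$low * 7, v$high * 7, v$spacing)
  m7 <- segment_vessels(v7, m)
  expect_identical(m7$vessel_mask, m$vessel_mask)
})

test_that("small components are removed and empty dermis yields empty mask", {
  low <- array(0, c(30, 20, 20))
  low[5:9, , ] <- 1                        # epidermis-like slab, 40-85 um
  low[20, 10, 10] <- 1                     # a single bright speck in the DE
  v <- dual_band_volume(low, array(0, dim(low)), c(10, 10, 10))
  m <- segment_dermis(v, detect_surface(v), 50, 150)
  m27 <- segment_vessels(v, m, min_size = 27)
  expect_equal(sum(m27$vessel_mask), 0)    # 1-voxel speck removed
  m1 <- segment_vessels(v, m, min_size = 1)
  expect_equal(sum(m1$vessel_mask), 1)
  # all-background dermis below a bright slab
  low0 <- array(0, c(30, 20, 20))
  low0[1:5, , ] <- 1
  v0 <- dual_band_volume(low0, array(0, dim(low0)), c(10, 10, 10))
  m0 <- segment_dermis(v0, detect_surface(v0), 50, 150)
  expect_equal(sum(segment_vessels(v0, m0)$vessel_mask), 0)
})
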