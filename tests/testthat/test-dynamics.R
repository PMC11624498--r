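test_that("percentage changes follow their definition and reconstruct", {
  co <- generate_cohort(3, effect = "paper_like", seed = 2)
  d <- suppressMessages(percent_change(co))
  expect_equal(nrow(d), 6 * 5 * 18)
  # spot-check the arithmetic on one entry
  s <- "H01"; f <- "avg_vessel_diameter"
  b <- co[[f]][co$subject == s & co$timepoint == "baseline"]
  x <- co[[f]][co$subject == s & co$timepoint == "hyp1"]
  expect_equal(d$delta[d$subject == s & d$feature == f &
                         d$timepoint == "hyp1"],
               100 * (x - b) / b)
  # adding baselines back reconstructs the follow-up values
  for (t in porh_timepoints()[-1]) {
    dd <- d[d$timepoint == t & d$feature == f, ]
    bb <- co[[f]][co$timepoint == "baseline"][match(dd$subject,
      co$subject[co$timepoint == "baseline"])]
    xx <- co[[f]][co$timepoint == t][match(dd$subject,
      co$subject[co$timepoint == t])]
    expect_equal(bb * (1 + dd$delta / 100), xx, tolerance = 1e-10)
  }
  # identical value -> zero change; zero baseline -> missing
  co2 <- as.data.frame(co)
  co2$de_area <- co2$de_area[match(co2$subject, co2$subject)]  # constant/subject
  co2$num_junctions[co2$subject == "H01" & co2$timepoint == "baseline"] <- 0
  d2 <- suppressMessages(percent_change(cohort_table(co2)))
  expect_true(all(d2$delta[d2$feature == "de_area"] == 0))
  expect_true(all(is.na(d2$delta[d2$subject == "H01" &
                                   d2$feature == "num_junctions"])))
})

test_that("group comparison matches the closed-form Student t", {
  gc <- group_compare(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(gc$t, -3.674, tolerance = 1e-3)
  expect_equal(gc$p, 0.0213, tolerance = 1e-3)
  expect_equal(gc$df, 4)
  # label swap negates t, keeps p
  gc2 <- group_compare(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(gc2$t, -gc$t)
  expect_equal(gc2$p, gc$p)
  # identical constant groups are degenerate with t = 0, p = 1
  gc3 <- group_compare(rep(2, 6), c(0, 0, 0, 1, 1, 1))
  expect_true(gc3$degenerate)
  expect_equal(gc3$t, 0)
  expect_equal(gc3$p, 1)
})

test_that("boxplot summaries use quartiles and 1.5 IQR whiskers", {
  x <- c(1, 2, 3, 4, 100)                  # 100 is an outlier
  gc <- group_compare(c(x, x + 1), rep(c(0, 1), each = 5))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(gc$median_0, q[2])
  expect_equal(gc$q1_0, q[1])
  expect_equal(gc$q3_0, q[3])
  expect_equal(gc$hi_0, max(x[x <= q[3] + 1.5 * (q[3] - q[1])]))
  expect_lt(gc$hi_0, 100)
})

test_that("type-I error is calibrated on null cohorts", {
  n_rej <- 0; n_tests <- 0
  for (seed in 1:20) {
    co <- generate_cohort(8, effect = "null", seed = seed)
    cmp <- compare_features(co, "baseline")
    n_rej <- n_rej + sum(cmp$p < 0.05)
    n_tests <- n_tests + nrow(cmp)
  }
  expect_gt(n_rej / n_tests, 0.01)
  expect_lt(n_rej / n_tests, 0.10)
})

test_that("scale aggregation averages within scale and flags degeneracy", {
  co <- generate_cohort(6, effect = "paper_like", seed = 5)
  # single-feature scale: aggregate equals that feature's normalized value
  sm <- feature_scales()
  sm[] <- "meso"
  sm["avg_junction_angle"] <- "micro"
  agg <- scale_aggregate(co, scale_map = sm)
  base <- co[co$timepoint == "baseline", ]
  x <- base$avg_junction_angle
  nx <- (x - min(x)) / (max(x) - min(x))
  micro <- agg$subject_values[agg$subject_values$scale == "micro", ]
  expect_equal(micro$baseline[match(base$subject, micro$subject)], nx)
  # constant feature across the cohort is dropped with a warning
  co2 <- as.data.frame(co)
  co2$de_area[co2$timepoint == "baseline"] <- 5
  expect_warning(scale_aggregate(cohort_table(co2)), "de_area")
})

test_that("a meso-only group effect is detected at the right scale", {
  eff <- effect_profile("null")
  meso <- names(feature_scales())[feature_scales() == "meso"]
  eff[meso, "hyp1"] <- -0.25
  hits <- 0
  for (seed in 1:10) {
    co <- generate_cohort(13, effect = eff, seed = seed)
    cmp <- scale_aggregate(co)$comparison
    at_hyp <- cmp[cmp$panel == "hyp1", ]
    ok <- at_hyp$p[at_hyp$scale == "meso"] < 0.05 &&
      at_hyp$p[at_hyp$scale == "micro"] > 0.05 &&
      at_hyp$p[at_hyp$scale == "macro"] > 0.05
    hits <- hits + ok
  }
  expect_gte(hits, 8)
})
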