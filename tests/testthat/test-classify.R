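test_that("univariate F ranking matches the anova oracle and handles ties", {
  set.seed(3)
  y <- rep(0:1, each = 6)
  X <- cbind(a = rnorm(12), b = y + rnorm(12, sd = 0.3),
             c = rnorm(12), d = y * 2 + rnorm(12, sd = 0.2))
  for (j in colnames(X)) {
    f_ref <- anova(lm(X[, j] ~ factor(y)))$`F value`[1]
    expect_equal(oneway_f(X[, j], y), f_ref, tolerance = 1e-10)
  }
  expect_equal(select_top_k(X, y, 1), "d")
  expect_setequal(select_top_k(X, y, 4), colnames(X))
  f_all <- apply(X, 2, oneway_f, g = y)
  expect_equal(select_top_k(X, y, 2),
               names(sort(f_all, decreasing = TRUE))[1:2])
  # constant features rank last
  X2 <- cbind(X, e = rep(1, 12))
  expect_false("e" %in% select_top_k(X2, y, 4))
  expect_error(select_top_k(X, y, 9), "k must be")
})

test_that("AUC equals exhaustive pairwise concordance", {
  expect_equal(auc_mw(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mw(rep(0.5, 6), rep(0:1, 3)), 0.5)
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(1:4, 1); n0 <- sample(1:4, 1)
    s <- c(sample(seq(0, 1, 0.1), n1 + n0, replace = TRUE))
    y <- c(rep(1, n1), rep(0, n0))
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    brute <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                         ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
    expect_equal(auc_mw(s, y), brute)
    # invariance under strictly monotone transforms, label-swap symmetry
    expect_equal(auc_mw(exp(3 * s), y), auc_mw(s, y))
    expect_equal(auc_mw(s, 1 - y), 1 - auc_mw(s, y))
  }
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
})

test_that("confusion metrics reproduce the derived published-style cells", {
  m <- confusion_metrics(12, 1, 11, 2)
  expect_equal(unname(m$rounded["accuracy"]), 0.88)
  expect_equal(unname(m$rounded["ppv"]), 0.86)
  expect_equal(unname(m$rounded["npv"]), 0.92)
  perfect <- confusion_metrics(13, 0, 13, 0)
  expect_true(all(perfect$metrics == 1))
  m2 <- confusion_metrics(6, 7, 10, 3)
  expect_equal(unname(m2$rounded["accuracy"]), 0.62)
  # label swap exchanges sensitivity/specificity and PPV/NPV
  a <- confusion_metrics(9, 4, 11, 2)$metrics
  b <- confusion_metrics(11, 2, 9, 4)$metrics
  expect_equal(unname(a["sensitivity"]), unname(b["specificity"]))
  expect_equal(unname(a["ppv"]), unname(b["npv"]))
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("confusion counts reconstructed from rounded rates are consistent", {
  rc <- reconstruct_confusion(0.92, 0.85, 13, 13)
  expect_equal(unname(rc), c(12, 1, 11, 2))
  m <- confusion_metrics(rc["tp"], rc["fn"], rc["tn"], rc["fp"])
  expect_equal(unname(round(m$metrics["sensitivity"], 2)), 0.92)
  expect_equal(unname(round(m$metrics["specificity"], 2)), 0.85)
})

test_that("LOSO separates a strong synthetic effect and stays honest on null", {
  co <- generate_cohort(8, effect = "strong", seed = 31)
  r <- loso_index(co, "hyp1", k = 9, seed = 31)
  expect_gte(r$auc, 0.9)
  expect_equal(length(r$index), 16)
  expect_true(all(r$index >= 0 & r$index <= 1))
  expect_equal(sum(r$importance), 1, tolerance = 1e-9)
  expect_true(all(r$selected$freq >= 0.5))
  # null cohort stays at chance level
  co0 <- generate_cohort(8, effect = "null", seed = 31)
  r0 <- loso_index(co0, "hyp1", k = 9, num_trees = 200, seed = 31)
  expect_gte(r0$auc, 0.2)
  expect_lte(r0$auc, 0.8)
})

test_that("permuted labels keep the pipeline at chance (leakage guard)", {
  co <- generate_cohort(5, effect = "strong", seed = 13)
  df <- as.data.frame(co)
  subj <- unique(df$subject)
  aucs <- numeric(12)
  set.seed(13)
  for (i in seq_along(aucs)) {
    perm <- sample(df$group[match(subj, df$subject)])
    df$group <- perm[match(df$subject, subj)]
    # keep both classes with >= 3 subjects
    while (sum(perm == 1) < 3 || sum(perm == 0) < 3) {
      perm <- sample(perm)
      df$group <- perm[match(df$subject, subj)]
    }
    aucs[i] <- loso_index(cohort_table(df), "hyp1", k = 5, num_trees = 150,
                          seed = i)$auc
  }
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("degenerate inputs are flagged not classifiable", {
  co <- as.data.frame(generate_cohort(4, effect = "null", seed = 3))
  base <- co$timepoint == "baseline"
  for (f in feature_names())                 # every change exactly zero
    co[[f]] <- co[[f]][base][match(co$subject, co$subject[base])]
  r <- loso_index(cohort_table(co), "occl1", k = 3, seed = 1)
  expect_true(r$not_classifiable)
  expect_true(is.na(r$auc))
})
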