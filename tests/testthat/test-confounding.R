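test_that("logistic deviance has its closed form for an intercept-only fit", {
  y <- rep(c(0, 1), each = 13)
  f <- fit_logistic(matrix(numeric(0), 26, 0), y)
  expect_equal(f$deviance, 52 * log(2), tolerance = 1e-9)
  expect_true(f$converged)
})

test_that("complete separation is flagged with vanishing deviance", {
  y <- rep(c(0, 1), each = 8)
  x <- as.numeric(y)                        # perfectly separating covariate
  f <- fit_logistic(cbind(x = x), y)
  expect_true(f$separation)
  expect_false(f$converged)
  expect_lt(f$deviance, 1e-4)
})

test_that("coefficients match an independent Newton optimizer on a toy set", {
  # overlapping classes so the MLE is finite
  x <- c(-1.5, -0.8, -0.2, 0.4, 0.6, 1.0, 1.3, 1.8)
  y <- c(0, 0, 1, 1, 0, 1, 1, 0)
  f <- fit_logistic(cbind(x = x), y)
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(f$coefficients), opt$par, tolerance = 1e-5)
  expect_equal(f$deviance, 2 * opt$value, tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the offending column", {
  y <- rep(c(0, 1), each = 6)
  x <- rnorm(12)
  expect_error(fit_logistic(cbind(a = x, b = 2 * x), y), "b")
  expect_error(multivariate_linear(data.frame(a = x, b = 2 * x),
                                   rnorm(12), y), "rank")
})

test_that("nested triplet deviances are monotone on random data", {
  set.seed(42)
  for (rep in 1:60) {
    n <- 24
    conf <- if (rep %% 2) rnorm(n) else rbinom(n, 1, 0.5)
    idx <- runif(n)
    y <- rbinom(n, 1, 0.3 + 0.4 * idx)
    if (length(unique(y)) < 2 || length(unique(conf)) < 2) next
    r <- suppressWarnings(nested_triplet(conf, idx, y))
    expect_gte(r$dev_m1, r$dev_m2 - 1e-6)
    expect_gte(r$dev_m2, r$dev_m3 - 1e-6)
    expect_gt(r$p_index, 0)
    expect_lte(r$p_index, 1)
  }
})

test_that("the triplet detects a strong index and ignores a null one", {
  set.seed(8)
  n <- 26
  conf <- rnorm(n, 65, 10)
  y <- rep(c(0, 1), each = 13)
  strong <- y + rnorm(n, sd = 0.15)
  r <- nested_triplet(conf, strong, y)
  expect_gt(r$dev_m1 - r$dev_m2, 10)
  expect_lt(r$p_index, 0.01)
  null_p <- replicate(40, {
    idx <- rnorm(n)
    nested_triplet(conf, idx, sample(y))$p_index
  })
  expect_gte(mean(null_p > 0.05), 0.75)
})

test_that("the linear probability model matches the normal-equations oracle", {
  set.seed(9)
  n <- 10
  covs <- data.frame(age = rnorm(n, 60, 8), bmi = rnorm(n, 25, 3))
  idx <- runif(n)
  y <- rbinom(n, 1, 0.5)
  while (var(y) == 0) y <- rbinom(n, 1, 0.5)
  tab <- multivariate_linear(covs, idx, y)
  X <- cbind(1, as.matrix(covs), idx)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(tab$estimate, as.numeric(beta), tolerance = 1e-8)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (n - ncol(X))
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(tab$se, unname(se), tolerance = 1e-8)
  # residual orthogonality to every design column
  expect_lt(max(abs(t(X) %*% resid)), 1e-8)
})

test_that("an index identical to the outcome fits exactly with coefficient 1", {
  set.seed(10)
  n <- 12
  y <- rep(c(0, 1), 6)
  covs <- data.frame(a = rnorm(n), b = rnorm(n))
  tab <- suppressWarnings(multivariate_linear(covs, y, y))  # exact fit
  expect_equal(tab$estimate[tab$term == "feature_index"], 1,
               tolerance = 1e-8)
  expect_lt(abs(tab$estimate[tab$term == "a"]), 1e-8)
})

test_that("sparse binary confounders are excluded from the multivariate model", {
  set.seed(12)
  n <- 26
  y <- rep(c(0, 1), each = 13)
  covs <- data.frame(age = rnorm(n, 65, 9),
                     diabetes = c(rep(0, 13), rbinom(13, 1, 0.15)))
  covs$diabetes[14] <- 1                     # ensure variation, sparse cell
  idx <- 0.2 + 0.6 * y + rnorm(n, sd = 0.2)
  res <- suppressMessages(confound_analysis(covs, idx, y))
  expect_true("diabetes" %in% res$excluded)
  expect_false(any(grepl("diabetes", res$linear_panel$term)))
  expect_true(all(res$glm_panel$dev_m1 >= res$glm_panel$dev_m2))
})
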