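#' Logistic regression fit with deviance reporting
#'
#' Maximum-likelihood logistic fit (binomial family, logit link, iteratively
#' reweighted least squares) of a binary outcome on a design matrix, with
#' the residual deviance (`-2 log L` at the MLE), a convergence flag, and a
#' complete-separation flag (fitted probabilities numerically at 0/1; the
#' deviance at the last iterate is still reported).
#'
#' @param X numeric design matrix (without intercept; one is added) or data
#'   frame.
#' @param y binary outcome in `{0, 1}`.
#' @param max_iter,tol IRLS control.
#' @return list with `coefficients`, `deviance`, `null_deviance`,
#'   `converged`, `separation`, `fit` (the `glm` object).
#' @export
fit_logistic <- function(X, y, max_iter = 100L, tol = 1e-10) {
  if (!all(y %in% c(0, 1))) stop_rv("outcome must be binary 0/1")
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[-qrD$pivot[seq_len(qrD$rank)]]
    stop_rv("rank-deficient design; collinear column(s): %s",
            paste(bad, collapse = ", "))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~",
                                 if (ncol(X)) paste(sprintf("`%s`",
                                                            colnames(X)),
                                                    collapse = " + ")
                                 else "1"))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(maxit = max_iter,
                                            epsilon = tol)))
  mu <- stats::fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8)
  list(coefficients = stats::coef(fit), deviance = fit$deviance,
       null_deviance = fit$null.deviance,
       converged = fit$converged && !separation,
       separation = separation, fit = fit)
}

#' Nested confounder / index / interaction model triplet
#'
#' Fits the three nested logistic models of the confounding analysis —
#' M1: `outcome ~ confounder`; M2: `+ index`; M3: `+ confounder:index` —
#' and reports each model's residual deviance plus likelihood-ratio p-values
#' (chi-squared, 1 df) for the term added in M2 (the index) and in M3 (the
#' interaction). Binary confounders with a sparse cell against the outcome
#' (any confounder x outcome cell below `min_cell`) are flagged.
#'
#' @param confounder numeric or binary covariate vector.
#' @param index per-subject feature-based index.
#' @param outcome binary outcome (1 = patient).
#' @param min_cell sparse-cell threshold for binary confounders.
#' @param wald use Wald instead of likelihood-ratio p-values.
#' @return one-row data frame: `dev_m1, dev_m2, dev_m3, p_index,
#'   p_interaction, sparse, interaction_degenerate, separation`.
#' @export
nested_triplet <- function(confounder, index, outcome, min_cell = 3L,
                           wald = FALSE) {
  if (length(unique(confounder)) < 2L || length(unique(index)) < 2L)
    stop_rv("confounder and index must vary")
  if (length(outcome) < 10L)
    stop_rv("need at least 10 subjects")
  m1 <- fit_logistic(cbind(confounder = confounder), outcome)
  m2 <- fit_logistic(cbind(confounder = confounder, index = index), outcome)
  # the interaction column can be numerically collinear with the confounder
  # (e.g. a binary confounder confined to one outcome class combined with a
  # near-separating index); the triplet then reports the M2 fit for M3 with
  # a degenerate-interaction flag instead of failing
  m3 <- tryCatch(
    fit_logistic(cbind(confounder = confounder, index = index,
                       `confounder:index` = confounder * index), outcome),
    error = function(e) NULL)
  m3_degenerate <- is.null(m3)
  if (m3_degenerate) m3 <- m2
  lrt_p <- function(d_big, d_small) {
    stat <- max(d_small - d_big, 0)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  if (wald) {
    wp <- function(fit, term) {
      s <- summary(fit$fit)$coefficients
      rn <- gsub("`", "", rownames(s))
      if (term %in% rn) s[match(term, rn), 4] else NA_real_
    }
    p_index <- wp(m2, "index")
    p_inter <- wp(m3, "confounder:index")
  } else {
    p_index <- lrt_p(m2$deviance, m1$deviance)
    p_inter <- lrt_p(m3$deviance, m2$deviance)
  }
  sparse <- FALSE
  if (all(confounder %in% c(0, 1))) {
    cells <- table(factor(confounder, levels = 0:1),
                   factor(outcome, levels = 0:1))
    sparse <- any(cells < min_cell)
  }
  if (sparse)
    warn_rv("sparse confounder x outcome cell (< %d); interpret with care",
            min_cell)
  if (m3_degenerate) p_inter <- 1   # no evidence for an interaction term
  data.frame(dev_m1 = m1$deviance, dev_m2 = m2$deviance,
             dev_m3 = m3$deviance, p_index = p_index,
             p_interaction = p_inter, sparse = sparse,
             interaction_degenerate = m3_degenerate,
             separation = m1$separation || m2$separation || m3$separation)
}

#' Multivariate linear probability model
#'
#' Ordinary least squares of the 0/1 outcome on the covariates plus the
#' feature-based index (linear probability form): coefficients, standard
#' errors from the residual variance, and two-sided t-test p-values.
#'
#' @param covariates data frame of covariate columns.
#' @param index per-subject feature-based index.
#' @param outcome binary outcome.
#' @return data frame `term, estimate, se, p` (intercept included).
#' @export
multivariate_linear <- function(covariates, index, outcome) {
  X <- cbind(as.data.frame(covariates), feature_index = index)
  D <- cbind(1, as.matrix(X))
  if (qr(D)$rank < ncol(D))
    stop_rv("rank-deficient design in the multivariate model")
  df <- data.frame(outcome = outcome, X, check.names = FALSE)
  fit <- stats::lm(outcome ~ ., data = df)
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             p = s[, 4], row.names = NULL)
}

#' Full confounding analysis
#'
#' Runs [nested_triplet()] for every covariate against the feature-based
#' index (upper panel) and [multivariate_linear()] on the non-sparse
#' covariates plus the index (lower panel). Binary covariates with any
#' confounder x outcome cell below `min_cell` are kept in the triplets but
#' excluded from the multivariate model, with a note.
#'
#' @param covariates data frame (columns such as age, sex, bmi,
#'   hypertension, smoking, hyperlipidemia, diabetes).
#' @param index per-subject feature-based index.
#' @param outcome binary outcome (1 = patient).
#' @param min_cell sparse-cell threshold.
#' @return list with `glm_panel` (one row per covariate), `linear_panel`,
#'   `excluded` (covariates dropped from the linear model).
#' @export
confound_analysis <- function(covariates, index, outcome, min_cell = 3L) {
  covariates <- as.data.frame(covariates)
  rows <- lapply(names(covariates), function(cn) {
    out <- withCallingHandlers(
      nested_triplet(covariates[[cn]], index, outcome, min_cell = min_cell),
      warning = function(w) invokeRestart("muffleWarning"))
    cbind(data.frame(confounder = cn), out)
  })
  glm_panel <- do.call(rbind, rows)
  excluded <- glm_panel$confounder[glm_panel$sparse]
  keep <- setdiff(names(covariates), excluded)
  linear_panel <- multivariate_linear(covariates[keep], index, outcome)
  if (length(excluded))
    message(sprintf("excluded from the multivariate model (sparse cells): %s",
                    paste(excluded, collapse = ", ")))
  list(glm_panel = glm_panel, linear_panel = linear_panel,
       excluded = excluded)
}
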