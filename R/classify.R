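#' One-way between-group F statistic per feature
#'
#' The univariate ANOVA F used to rank features for top-k selection
#' (between-group over within-group mean squares). Constant features have an
#' undefined F and are ranked last.
#'
#' @param x numeric vector.
#' @param g binary group labels.
#' @return F statistic (NaN for degenerate input).
#' @export
oneway_f <- function(x, g) {
  keep <- !is.na(x)
  x <- x[keep]; g <- g[keep]
  groups <- split(x, g)
  if (length(groups) < 2L) return(NaN)
  n <- lengths(groups)
  gm <- mean(x)
  ssb <- sum(n * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- length(x) - length(groups)
  if (dfw <= 0L || ssw == 0) return(NaN)
  (ssb / dfb) / (ssw / dfw)
}

#' Select the top-k features by univariate F ranking
#'
#' Ranks the columns of the training matrix by [oneway_f()] against the
#' training labels (undefined F ranks last) and returns the `k` top-ranked
#' column names; ties break deterministically by column order.
#'
#' @param X numeric matrix or data frame, subjects x features.
#' @param y binary labels.
#' @param k number of features, `1 <= k <= ncol(X)`.
#' @return character vector of selected column names (length `k`).
#' @export
select_top_k <- function(X, y, k) {
  X <- as.matrix(X)
  if (k < 1 || k > ncol(X)) stop_rv("k must be in [1, %d]", ncol(X))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop_rv("training labels must contain both classes")
  f <- apply(X, 2, oneway_f, g = y)
  f[!is.finite(f)] <- -Inf
  ord <- order(-f, seq_along(f))
  colnames(X)[ord[seq_len(k)]]
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen diseased subject's index exceeds a
#' randomly chosen healthy subject's, with ties counted one half — computed
#' from midranks, which equals exhaustive pair enumeration.
#'
#' @param index numeric scores.
#' @param labels binary labels (1 = diseased).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(index, labels) {
  keep <- !is.na(index) & !is.na(labels)
  index <- index[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop_rv("both classes must be present")
  r <- rank(index, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metric suite
#'
#' Standard derived metrics from integer confusion counts, reported at full
#' precision and rounded to 2 decimals. Undefined ratios (empty predicted
#' class) are `NA` and flagged.
#'
#' @param tp,fn,tn,fp non-negative integer counts; `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return list with `counts`, `metrics` (full precision), `rounded`
#'   (2 decimals) and `flags`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  cnt <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop_rv("counts must be non-negative integers")
  if (tp + fn == 0 || tn + fp == 0)
    stop_rv("each true class must be non-empty")
  m <- c(accuracy = (tp + tn) / sum(cnt),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  flags <- c(ppv_undefined = tp + fp == 0, npv_undefined = tn + fn == 0)
  list(counts = cnt, metrics = m, rounded = round(m, 2), flags = flags)
}

#' Reconstruct integer confusion counts from printed sensitivity/specificity
#'
#' Given rounded sensitivity and specificity and the per-class sizes,
#' returns the integer counts `(tp, fn, tn, fp)` whose exact ratios round to
#' the printed values (the nearest integer to `sens * n_pos` etc.).
#'
#' @param sensitivity,specificity printed (rounded) values.
#' @param n_pos,n_neg true class sizes.
#' @return named integer vector `(tp, fn, tn, fp)`.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos = 13L,
                                  n_neg = 13L) {
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  c(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' Leave-one-subject-out feature-selected random-forest disease index
#'
#' For a chosen PORH timepoint, classifies patients vs healthy from the
#' percentage changes of the 18 features at that timepoint (raw feature
#' values when `timepoint = "baseline"`). In every LOSO fold, the top-k
#' features are selected by [select_top_k()] on the training subjects only
#' (no leakage), a probability random forest is fitted on them, and the
#' held-out subject's class-1 probability becomes their out-of-fold index.
#' With `k = "auto"` the full LOSO is repeated for every `k` in 1..18 and
#' the `k` maximizing the out-of-fold AUC is kept (smallest `k` on ties).
#' The reported feature set contains the features selected in at least half
#' the folds at the final `k`; their relative importances come from a forest
#' refitted on all subjects with those features, normalized to sum 1.
#'
#' A timepoint whose inputs are degenerate (all changes missing, or no
#' between-subject variation) is returned flagged `not_classifiable` with
#' `NA` metrics.
#'
#' @param cohort a [cohort_table()] (or a precomputed [percent_change()]
#'   table via `delta`).
#' @param timepoint one of [porh_timepoints()].
#' @param k integer 1..18 or `"auto"`.
#' @param num_trees random-forest size.
#' @param threshold index cutoff for the confusion matrix.
#' @param seed integer seed propagated to every forest fit.
#' @param delta optional precomputed delta table.
#' @return object of class `index_result`: list with `timepoint`, `k`,
#'   `index` (named per-subject out-of-fold probabilities), `labels`, `auc`,
#'   `metrics` (from [confusion_metrics()]), `selected` (data frame
#'   `feature, freq`), `importance` (named, sums to 1), `threshold`,
#'   `not_classifiable`.
#' @export
loso_index <- function(cohort, timepoint = "hyp1", k = "auto",
                       num_trees = 500L, threshold = 0.5, seed = 1,
                       delta = NULL) {
  cohort <- cohort_table(as.data.frame(cohort))
  fn <- feature_names()
  subj <- unique(cohort$subject)
  lab <- cohort$group[match(subj, cohort$subject)]
  if (sum(lab == 0) < 3L || sum(lab == 1) < 3L)
    stop_rv("need at least 3 subjects per group for LOSO")
  if (timepoint == "baseline") {
    d <- cohort[cohort$timepoint == "baseline", ]
    X <- as.matrix(d[match(subj, d$subject), fn])
  } else {
    if (!timepoint %in% porh_timepoints())
      stop_rv("unknown timepoint '%s'", timepoint)
    delta <- delta %||% suppressMessages(percent_change(cohort))
    d <- delta[delta$timepoint == timepoint, ]
    X <- matrix(NA_real_, length(subj), length(fn),
                dimnames = list(subj, fn))
    for (f in fn)
      X[, f] <- d$delta[d$feature == f][match(subj, d$subject[d$feature == f])]
  }
  rownames(X) <- subj
  usable <- colSums(is.na(X)) == 0 & apply(X, 2, stats::sd, na.rm = TRUE) > 0
  if (!any(usable))
    return(structure(list(timepoint = timepoint, k = NA, index = NULL,
                          labels = stats::setNames(lab, subj), auc = NA,
                          metrics = NULL, selected = NULL,
                          importance = NULL, threshold = threshold,
                          not_classifiable = TRUE),
                     class = "index_result"))
  X <- X[, usable, drop = FALSE]
  p <- ncol(X)
  n <- nrow(X)

  # per-fold feature ranking is independent of k: rank once per fold
  fold_rank <- vector("list", n)
  for (i in seq_len(n)) {
    f <- apply(X[-i, , drop = FALSE], 2, oneway_f, g = lab[-i])
    f[!is.finite(f)] <- -Inf
    fold_rank[[i]] <- colnames(X)[order(-f, seq_len(p))]
  }

  run_k <- function(kk) {
    idx <- numeric(n)
    sel <- vector("list", n)
    for (i in seq_len(n)) {
      feats <- fold_rank[[i]][seq_len(kk)]
      sel[[i]] <- feats
      ytr <- factor(lab[-i], levels = 0:1)
      # stratified class-balanced bootstrap: leaving one subject out makes
      # its class underrepresented in training, which would bias the
      # out-of-fold probability against it; drawing equal counts per class
      # for every tree removes that imbalance
      nmin <- min(table(ytr))
      fit <- ranger::ranger(
        x = X[-i, feats, drop = FALSE], y = ytr,
        sample.fraction = 0.8 * nmin / as.numeric(table(ytr)),
        num.trees = num_trees, probability = TRUE,
        seed = child_seed(seed, paste0("fold-", i)), num.threads = 1L)
      idx[i] <- stats::predict(fit,
                               data = X[i, feats, drop = FALSE])$predictions[, "1"]
    }
    list(index = idx, sel = sel)
  }

  if (identical(k, "auto")) {
    best <- NULL
    for (kk in seq_len(p)) {
      r <- run_k(kk)
      a <- auc_mw(r$index, lab)
      if (is.null(best) || a > best$auc + 1e-12) {
        best <- list(k = kk, auc = a, res = r)
      }
    }
    k <- best$k
    res <- best$res
  } else {
    k <- as.integer(k)
    if (k < 1L || k > p) stop_rv("k must be in [1, %d]", p)
    res <- run_k(k)
  }

  idx <- stats::setNames(res$index, subj)
  a <- auc_mw(idx, lab)
  pred <- as.integer(idx >= threshold)
  cm <- confusion_metrics(tp = sum(pred == 1 & lab == 1),
                          fn = sum(pred == 0 & lab == 1),
                          tn = sum(pred == 0 & lab == 0),
                          fp = sum(pred == 1 & lab == 0))
  freq <- table(unlist(res$sel)) / n
  selected <- names(freq)[freq >= 0.5]
  selected <- selected[order(match(selected, fn))]
  sel_freq <- as.numeric(freq[selected])
  imp <- NULL
  if (length(selected)) {
    refit <- ranger::ranger(
      x = X[, selected, drop = FALSE], y = factor(lab, levels = 0:1),
      num.trees = num_trees, probability = TRUE, importance = "impurity",
      seed = child_seed(seed, "refit"), num.threads = 1L)
    imp <- refit$variable.importance
    imp <- pmax(imp, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  structure(list(timepoint = timepoint, k = k, index = idx,
                 labels = stats::setNames(lab, subj), auc = a,
                 metrics = cm,
                 selected = data.frame(feature = selected, freq = sel_freq),
                 importance = imp, threshold = threshold,
                 not_classifiable = FALSE),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  if (x$not_classifiable) {
    cat(sprintf("<index_result> %s: not classifiable (degenerate inputs)\n",
                x$timepoint))
    return(invisible(x))
  }
  cat(sprintf("<index_result> %s: k = %d, AUC = %.3f, accuracy = %.2f\n",
              x$timepoint, x$k, x$auc, x$metrics$metrics["accuracy"]))
  invisible(x)
}

#' Classification performance across the PORH timeline
#'
#' Runs [loso_index()] at every post-baseline timepoint and assembles a
#' per-minute performance table (selected-feature count, AUC, accuracy,
#' sensitivity, specificity, PPV, NPV).
#'
#' @inheritParams loso_index
#' @return list with `table` (data frame, one column per timepoint) and
#'   `results` (the per-timepoint `index_result`s).
#' @export
classification_timeline <- function(cohort, k = "auto", num_trees = 500L,
                                    threshold = 0.5, seed = 1) {
  tps <- porh_timepoints()[-1]
  delta <- suppressMessages(percent_change(cohort))
  results <- lapply(tps, function(t)
    loso_index(cohort, t, k = k, num_trees = num_trees,
               threshold = threshold, seed = seed, delta = delta))
  names(results) <- tps
  row <- function(r) {
    if (r$not_classifiable) return(rep(NA_real_, 7))
    c(r$k, r$auc, r$metrics$metrics)
  }
  tab <- vapply(results, row, double(7))
  rownames(tab) <- c("n_selected", "auc", "accuracy", "sensitivity",
                     "specificity", "ppv", "npv")
  list(table = as.data.frame(tab), results = results)
}
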