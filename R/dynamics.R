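#' Percentage change of every feature relative to baseline
#'
#' For each subject and feature, computes the five post-baseline values
#' `delta = 100 * (f_t - f_baseline) / f_baseline`. Entries with a zero or
#' missing baseline (or missing follow-up value) are `NA`; their count is
#' reported via `message()`.
#'
#' @param cohort a [cohort_table()].
#' @return long data frame of class `delta_table`: `subject, group,
#'   timepoint, feature, delta` with the five post-baseline timepoints per
#'   subject and feature.
#' @export
percent_change <- function(cohort) {
  cohort <- cohort_table(as.data.frame(cohort))
  tp_post <- porh_timepoints()[-1]
  fn <- feature_names()
  base <- cohort[cohort$timepoint == "baseline", c("subject", fn)]
  rows <- list()
  n_missing <- 0L
  for (t in tp_post) {
    cur <- cohort[cohort$timepoint == t, c("subject", "group", fn)]
    cur <- cur[match(base$subject, cur$subject), ]
    for (f in fn) {
      b <- base[[f]]
      x <- cur[[f]]
      delta <- ifelse(!is.na(b) & b != 0 & !is.na(x),
                      100 * (x - b) / b, NA_real_)
      n_missing <- n_missing + sum(is.na(delta))
      rows[[length(rows) + 1L]] <-
        data.frame(subject = base$subject, group = cur$group,
                   timepoint = t, feature = f, delta = delta)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, match(out$timepoint, porh_timepoints()),
                   match(out$feature, fn)), ]
  rownames(out) <- NULL
  if (n_missing > 0L)
    message(sprintf("percent_change: %d undefined entries (zero or missing baseline)",
                    n_missing))
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Two-group comparison of per-subject scalars
#'
#' Unpaired two-sided Student's t-test (equal-variance by default; Welch via
#' `var_equal = FALSE`) plus the boxplot summary of each group (median,
#' quartiles, whiskers at 1.5 times the interquartile range). When both
#' groups are constant with identical values the comparison is degenerate:
#' `t = 0`, `p = 1`, flagged.
#'
#' @param values numeric per-subject scalars.
#' @param labels group labels (0 = healthy, 1 = patient), same length.
#' @param var_equal classic Student (TRUE) or Welch (FALSE).
#' @return one-row data frame: group means, `t`, `df`, `p`, per-group
#'   boxplot columns (`median`, `q1`, `q3`, `lo`, `hi` with suffixes `_0`,
#'   `_1`), `n_0`, `n_1`, `degenerate`.
#' @export
group_compare <- function(values, labels, var_equal = TRUE) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  g0 <- values[labels == 0]
  g1 <- values[labels == 1]
  if (length(g0) < 2L || length(g1) < 2L)
    stop_rv("need at least 2 subjects per group")
  degen <- stats::var(g0) == 0 && stats::var(g1) == 0
  if (degen && mean(g0) == mean(g1)) {
    tt <- list(statistic = 0, parameter = length(values) - 2L, p.value = 1)
  } else {
    ht <- stats::t.test(g0, g1, var.equal = var_equal)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  bx <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    c(median = q[2], q1 = q[1], q3 = q[3], lo = lo, hi = hi)
  }
  b0 <- bx(g0); b1 <- bx(g1)
  data.frame(mean_0 = mean(g0), mean_1 = mean(g1),
             t = tt$statistic, df = tt$parameter, p = tt$p.value,
             median_0 = b0["median"], q1_0 = b0["q1"], q3_0 = b0["q3"],
             lo_0 = b0["lo"], hi_0 = b0["hi"],
             median_1 = b1["median"], q1_1 = b1["q1"], q3_1 = b1["q3"],
             lo_1 = b1["lo"], hi_1 = b1["hi"],
             n_0 = length(g0), n_1 = length(g1),
             degenerate = degen, row.names = NULL)
}

#' Per-feature group comparison at one timepoint
#'
#' Applies [group_compare()] to every feature, either on raw baseline values
#' (`timepoint = "baseline"`) or on percentage changes at a post-baseline
#' timepoint. No multiple-testing correction is applied by default (the
#' per-feature p-value presentation); `p_adjust = "BH"` adds a
#' Benjamini-Hochberg column.
#'
#' @param cohort a [cohort_table()].
#' @param timepoint one of [porh_timepoints()].
#' @param delta optional precomputed [percent_change()] table.
#' @param p_adjust `"none"` or a method of [stats::p.adjust()].
#' @return data frame with one row per feature (`feature`, `scale`, then the
#'   [group_compare()] columns, plus `p_adj` unless `p_adjust = "none"`).
#' @export
compare_features <- function(cohort, timepoint = "hyp1", delta = NULL,
                             p_adjust = "none") {
  cohort <- cohort_table(as.data.frame(cohort))
  if (!timepoint %in% porh_timepoints())
    stop_rv("unknown timepoint '%s'", timepoint)
  fn <- feature_names()
  sc <- feature_scales()
  rows <- lapply(fn, function(f) {
    if (timepoint == "baseline") {
      d <- cohort[cohort$timepoint == "baseline", ]
      vals <- d[[f]]
      labs <- d$group
    } else {
      delta <- delta %||% suppressMessages(percent_change(cohort))
      d <- delta[delta$timepoint == timepoint & delta$feature == f, ]
      vals <- d$delta
      labs <- d$group
    }
    cbind(data.frame(feature = f, scale = unname(sc[f])),
          group_compare(vals, labs))
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, p_adjust)
  out
}

#' Scale-of-detail aggregation and comparison
#'
#' Baseline panel: each feature is min-max normalized across the cohort's
#' baseline values (constant features are dropped with a warning), then
#' averaged within each scale per subject. Hyperemia panel: percentage
#' changes at `timepoint` are averaged (unweighted) within each scale per
#' subject. [group_compare()] is applied per scale in both panels.
#'
#' @param cohort a [cohort_table()].
#' @param delta optional precomputed [percent_change()] table.
#' @param scale_map named character vector mapping all 18 features to
#'   scales; default [feature_scales()].
#' @param timepoint post-baseline timepoint for the change panel.
#' @return list with `subject_values` (data frame `subject, group, scale,
#'   baseline, delta`) and `comparison` (per scale x panel
#'   [group_compare()] rows).
#' @export
scale_aggregate <- function(cohort, delta = NULL,
                            scale_map = feature_scales(),
                            timepoint = "hyp1") {
  cohort <- cohort_table(as.data.frame(cohort))
  fn <- feature_names()
  if (!all(fn %in% names(scale_map)))
    stop_rv("scale_map must cover all 18 features")
  delta <- delta %||% suppressMessages(percent_change(cohort))
  base <- cohort[cohort$timepoint == "baseline", ]
  norm <- list()
  dropped <- character(0)
  for (f in fn) {
    x <- base[[f]]
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (!is.finite(lo) || hi <= lo) { dropped <- c(dropped, f); next }
    norm[[f]] <- (x - lo) / (hi - lo)
  }
  if (length(dropped))
    warn_rv("constant features dropped from baseline normalization: %s",
            paste(dropped, collapse = ", "))
  scales <- unique(unname(scale_map[fn]))
  rows <- list()
  for (s in scales) {
    fs <- intersect(fn[scale_map[fn] == s], names(norm))
    if (length(fs) == 0L) stop_rv("scale '%s' has no usable features", s)
    bmat <- do.call(cbind, norm[fs])
    bagg <- rowMeans(bmat, na.rm = TRUE)
    d <- delta[delta$timepoint == timepoint &
                 delta$feature %in% fn[scale_map[fn] == s], ]
    dm <- tapply(d$delta, d$subject, mean, na.rm = TRUE)
    rows[[s]] <- data.frame(subject = base$subject, group = base$group,
                            scale = s, baseline = bagg,
                            delta = as.numeric(dm[base$subject]))
  }
  sv <- do.call(rbind, rows)
  rownames(sv) <- NULL
  comp <- do.call(rbind, lapply(scales, function(s) {
    d <- sv[sv$scale == s, ]
    rbind(cbind(data.frame(scale = s, panel = "baseline"),
                group_compare(d$baseline, d$group)),
          cbind(data.frame(scale = s, panel = timepoint),
                group_compare(d$delta, d$group)))
  }))
  list(subject_values = sv, comparison = comp)
}
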