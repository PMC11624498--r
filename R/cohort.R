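#' The 18 dermal microvascular features
#'
#' Canonical names, units and scale-of-detail labels of the 18 morphometric
#' features computed per RSOM volume. Scales follow the three classes of
#' detail: `micro` (single-vessel parameters such as diameter or volume),
#' `meso` (network organization such as branch counts or junction density),
#' `macro` (whole-layer parameters such as dermis thickness or mean signal).
#' The mapping is a package default and can be overridden wherever a
#' `scale_map` argument is accepted.
#'
#' @return `feature_names()`: character vector of 18 names in canonical
#'   order. `feature_scales()`: named character vector mapping each feature
#'   to `"micro"`, `"meso"` or `"macro"`.
#' @export
feature_names <- function() {
  c("avg_junction_angle", "avg_vessel_length", "avg_tortuosity",
    "length_to_width_ratio", "avg_vessel_diameter", "avg_vessel_volume",
    "num_vessels", "junction_density", "vascular_density",
    "junctions_to_vessels_ratio", "num_j2j_branches", "num_j2e_branches",
    "num_junctions", "de_thickness", "total_vessel_area",
    "mean_signal_vessels", "mean_signal_de", "de_area")
}

#' @rdname feature_names
#' @export
feature_scales <- function() {
  fn <- feature_names()
  stats::setNames(c(rep("micro", 6L), rep("meso", 7L), rep("macro", 5L)), fn)
}

#' Feature units (documentation helper)
#' @return named character vector of units per feature.
#' @export
feature_units <- function() {
  stats::setNames(
    c("degrees", "um", "unitless", "unitless", "um", "um^3", "count",
      "mm^-3", "fraction", "unitless", "count", "count", "count", "um",
      "mm^2", "a.u.", "a.u.", "mm^2"),
    feature_names())
}

#' PORH timepoint labels
#'
#' The six-image acquisition protocol: one baseline scan, three scans during
#' arterial occlusion (one per minute of cuff inflation), and two during the
#' hyperemia period after cuff release.
#' @return character vector of the six labels in protocol order.
#' @export
porh_timepoints <- function() {
  c("baseline", "occl1", "occl2", "occl3", "hyp1", "hyp2")
}

covariate_names <- function() {
  c("age", "sex", "bmi", "hypertension", "smoking", "hyperlipidemia",
    "diabetes")
}

#' Cohort feature table
#'
#' A validated wide data frame with one row per subject x timepoint: subject
#' id, group (0 = healthy, 1 = patient), the seven demographic/clinical
#' covariates, the timepoint label and the 18 feature columns. This is the
#' in-memory unit consumed by the dynamics, classification and confounding
#' stages.
#'
#' @param df data frame with columns `subject`, `group`, the covariates
#'   (`age`, `sex`, `bmi`, `hypertension`, `smoking`, `hyperlipidemia`,
#'   `diabetes`), `timepoint` and the 18 features of [feature_names()].
#' @return the data frame with class `cohort_table`, rows ordered by subject
#'   then protocol timepoint.
#' @export
cohort_table <- function(df) {
  need <- c("subject", "group", covariate_names(), "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_rv("missing cohort columns: %s", paste(miss, collapse = ", "))
  fmiss <- setdiff(feature_names(), names(df))
  if (length(fmiss))
    stop_rv("missing feature columns: %s", paste(fmiss, collapse = ", "))
  extra <- setdiff(names(df), c(need, feature_names()))
  if (length(extra))
    stop_rv("unknown columns: %s", paste(extra, collapse = ", "))
  df$subject <- as.character(df$subject)
  df$timepoint <- as.character(df$timepoint)
  bad_tp <- setdiff(unique(df$timepoint), porh_timepoints())
  if (length(bad_tp))
    stop_rv("unknown timepoint labels: %s", paste(bad_tp, collapse = ", "))
  cnt <- table(df$subject)
  bad <- names(cnt)[cnt != 6L]
  if (length(bad))
    stop_rv("subjects without exactly 6 timepoints: %s",
            paste(bad, collapse = ", "))
  for (s in unique(df$subject)) {
    tps <- sort(match(df$timepoint[df$subject == s], porh_timepoints()))
    if (!identical(tps, 1:6))
      stop_rv("subject %s does not cover the six protocol timepoints", s)
  }
  if (!all(df$group %in% c(0, 1)))
    stop_rv("group must be 0 (healthy) or 1 (patient)")
  df <- df[order(df$subject, match(df$timepoint, porh_timepoints())),
           c(need, feature_names())]
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write cohort feature tables
#'
#' The canonical on-disk layout is a long-format CSV (UTF-8, `.` decimal,
#' comma separated) with columns `subject, group, age, sex, bmi,
#' hypertension, smoking, hyperlipidemia, diabetes, timepoint, feature,
#' value` (covariates repeated on every row); a wide layout with the 18
#' features as columns is also read and can be written with
#' `format = "wide"`. Values are serialized with 15 significant digits, so a
#' write/read round trip preserves them to at least 12 significant digits and
#' rewriting an unmodified table is byte-identical.
#'
#' @param path CSV path.
#' @param tab a [cohort_table()].
#' @param format `"long"` (canonical) or `"wide"`.
#' @return `read_feature_table` returns a [cohort_table()];
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_rv("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("feature" %in% names(df)) {
    bad <- setdiff(unique(df$feature), feature_names())
    if (length(bad))
      stop_rv("unknown feature column(s): %s", paste(bad, collapse = ", "))
    ids <- c("subject", "group", covariate_names(), "timepoint")
    wide <- stats::reshape(df, idvar = ids, timevar = "feature",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    df <- wide
  }
  cohort_table(df)
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(tab, path, format = c("long", "wide")) {
  format <- match.arg(format)
  tab <- cohort_table(as.data.frame(tab))
  fmt <- function(x) {
    out <- vapply(x, function(v)
      if (is.na(v)) "" else sprintf("%.15g", v), character(1))
    out
  }
  if (format == "long") {
    ids <- c("subject", "group", covariate_names(), "timepoint")
    rows <- lapply(feature_names(), function(f) {
      d <- tab[ids]
      d$feature <- f
      d$value <- tab[[f]]
      d
    })
    long <- do.call(rbind, rows)
    long <- long[order(long$subject,
                       match(long$timepoint, porh_timepoints()),
                       match(long$feature, feature_names())), ]
    long$value <- fmt(long$value)
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- tab
    for (f in feature_names()) out[[f]] <- fmt(out[[f]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
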