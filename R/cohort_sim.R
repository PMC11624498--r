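# Feature-level cohort simulation: a fast shortcut that emulates the
# statistical structure of an imaging cohort (identical baseline feature
# distributions in both groups, group-dependent hyperemic reactivity,
# demographic covariates with configurable imbalance) without rasterizing
# volumes. Used to exercise the dynamics, classification and confounding
# stages at realistic sample sizes.

# baseline medians and coefficients of variation for the 18 features,
# chosen as plausible magnitudes for a 4x2 mm forearm scan
feature_baseline_defaults <- function() {
  fn <- feature_names()
  data.frame(
    feature = fn,
    median = c(110, 250, 1.15, 6, 40, 3e5, 120, 300, 0.12, 0.45,
               60, 50, 55, 450, 2.5, 0.35, 0.15, 1.5),
    cv = c(0.08, 0.20, 0.05, 0.20, 0.20, 0.30, 0.25, 0.25, 0.25, 0.15,
           0.30, 0.30, 0.30, 0.15, 0.20, 0.25, 0.25, 0.15))
}

# common hyperemic dynamics applied to every feature (fractional change per
# timepoint): near-baseline in occlusion minute 1, mild reduction later in
# occlusion, overshoot after cuff release
phase_dynamics_default <- function() {
  stats::setNames(c(0, 0, -0.05, -0.08, 0.25, 0.10), porh_timepoints())
}

#' Named group-effect presets for cohort simulation
#'
#' Patient-minus-healthy offsets on the fractional change of each feature at
#' each timepoint. `"null"`: no group effect anywhere. `"paper_like"`: a
#' blunted patient response (moderate negative offsets) on 9 features
#' spanning all three scales at the two hyperemia timepoints.
#' `"strong"`: a 2-standard-deviation downward shift (relative to the
#' generator noise `noise_sd = 0.08`) on the same 9 features at hyperemia
#' minute 1, plus half that at minute 2.
#'
#' @param name preset name.
#' @param noise_sd the generator noise level the shift is calibrated to.
#' @return matrix 18 features x 6 timepoints of offsets (class
#'   `effect_profile`).
#' @export
effect_profile <- function(name = c("null", "paper_like", "strong"),
                           noise_sd = 0.08) {
  name <- match.arg(name)
  fn <- feature_names()
  tp <- porh_timepoints()
  m <- matrix(0, length(fn), length(tp), dimnames = list(fn, tp))
  affected <- c("avg_vessel_length", "avg_vessel_diameter",
                "avg_vessel_volume", "num_vessels", "vascular_density",
                "num_j2j_branches", "num_junctions", "total_vessel_area",
                "de_area")
  if (name == "paper_like") {
    m[affected, "hyp1"] <- -0.12
    m[affected, "hyp2"] <- -0.06
  } else if (name == "strong") {
    m[affected, "hyp1"] <- -2 * noise_sd
    m[affected, "hyp2"] <- -1 * noise_sd
  }
  structure(m, class = c("effect_profile", class(m)), preset = name)
}

#' Demographic covariate model
#'
#' Group-specific sampling distributions for the seven covariates: age and
#' BMI normal, the binaries Bernoulli. Defaults mirror a small
#' carotid-disease case-control cohort (patients older, more often male,
#' hypertensive and smokers; hyperlipidemia balanced; diabetes rare and
#' absent in controls), which gives the confounding stage realistic group
#' imbalance and sparse-cell cases.
#'
#' @param age_mean,age_sd,bmi_mean,bmi_sd length-2 vectors
#'   `(healthy, patient)`.
#' @param p_male,p_hypertension,p_smoking,p_hyperlipidemia,p_diabetes
#'   length-2 probability vectors `(healthy, patient)`.
#' @return list of class `covariate_model`.
#' @export
covariate_model <- function(age_mean = c(64.5, 70.2), age_sd = c(10.5, 9.0),
                            bmi_mean = c(25.3, 26.0), bmi_sd = c(4.0, 2.7),
                            p_male = c(5 / 13, 9 / 13),
                            p_hypertension = c(4 / 13, 10 / 13),
                            p_smoking = c(0 / 13, 4 / 13),
                            p_hyperlipidemia = c(2 / 13, 2 / 13),
                            p_diabetes = c(0 / 13, 2 / 13)) {
  structure(list(age_mean = age_mean, age_sd = age_sd, bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd, p_male = p_male,
                 p_hypertension = p_hypertension, p_smoking = p_smoking,
                 p_hyperlipidemia = p_hyperlipidemia,
                 p_diabetes = p_diabetes),
            class = "covariate_model")
}

#' Simulate a feature-level PORH cohort
#'
#' Draws baseline features from log-normal distributions identical across
#' groups (so baseline group comparisons are null by construction), then
#' evolves each feature along the PORH timeline as
#' `f_t = f_baseline * (1 + phase_t + group * effect[f, t] + eps)` with
#' `eps ~ N(0, noise_sd)` independent per subject, feature and post-baseline
#' timepoint. Covariates are drawn from a [covariate_model()].
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effect an [effect_profile()] matrix (or preset name).
#' @param noise_sd fractional-change noise SD.
#' @param phase named per-timepoint common dynamics (fractions).
#' @param covariates a [covariate_model()].
#' @param seed integer seed.
#' @return a [cohort_table()].
#' @export
generate_cohort <- function(n_per_group = 13, effect = "paper_like",
                            noise_sd = 0.08,
                            phase = phase_dynamics_default(),
                            covariates = covariate_model(), seed = 1) {
  if (n_per_group < 2) stop_rv("n_per_group must be >= 2")
  if (is.character(effect)) effect <- effect_profile(effect, noise_sd)
  fb <- feature_baseline_defaults()
  fn <- feature_names()
  tp <- porh_timepoints()
  set.seed(child_seed(seed, "cohort"))
  rows <- list()
  for (g in 0:1) {
    gi <- g + 1L
    for (i in seq_len(n_per_group)) {
      subj <- sprintf("%s%02d", c("H", "P")[gi], i)
      cov <- data.frame(
        subject = subj, group = g,
        age = stats::rnorm(1, covariates$age_mean[gi], covariates$age_sd[gi]),
        sex = stats::rbinom(1, 1, covariates$p_male[gi]),
        bmi = stats::rnorm(1, covariates$bmi_mean[gi], covariates$bmi_sd[gi]),
        hypertension = stats::rbinom(1, 1, covariates$p_hypertension[gi]),
        smoking = stats::rbinom(1, 1, covariates$p_smoking[gi]),
        hyperlipidemia = stats::rbinom(1, 1, covariates$p_hyperlipidemia[gi]),
        diabetes = stats::rbinom(1, 1, covariates$p_diabetes[gi]))
      base <- stats::rlnorm(length(fn), log(fb$median),
                            sqrt(log(1 + fb$cv^2)))
      for (t in seq_along(tp)) {
        eps <- if (t == 1L) rep(0, length(fn))
               else stats::rnorm(length(fn), 0, noise_sd)
        val <- base * (1 + phase[[tp[t]]] + g * effect[, tp[t]] + eps)
        val <- pmax(val, 0.01 * base)
        row <- cbind(cov, timepoint = tp[t],
                     as.data.frame(as.list(stats::setNames(val, fn))))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  cohort_table(do.call(rbind, rows))
}
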