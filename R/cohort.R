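#' Configuration for the synthetic stroke cohort generator
#'
#' Builds the parameter set consumed by [generate_cohort()]. The defaults
#' emulate the marginal structure of a two-centre acute anterior-circulation
#' stroke cohort dichotomised at the 4.5 h intravenous-thrombolysis window:
#' 358 patients imaged within 4.5 h of witnessed onset and 275 beyond it,
#' skewed onset-to-MRI times with medians 3.5 h and 7.5 h, per-group
#' covariate prevalences (e.g. hyperlipemia 9.2% vs 35.6%, large vessel
#' occlusion 31.0% vs 64.4%), and a FLAIR signal-intensity ratio (SIR) that
#' rises with log lesion age and with LVO.
#'
#' The SIR generative model is
#' \deqn{SIR = \beta_0 + \beta_1 \log(1 + t) + \beta_2 \cdot LVO +
#'       \epsilon,\quad \epsilon \sim N(0, \sigma^2),}
#' censored below at 1 (a lesion is not systematically darker than its
#' mirror tissue). The DWI-FLAIR mismatch flag is a thresholded surrogate
#' for the human visual rating: mismatch is present when SIR falls below
#' `mismatch_threshold`.
#'
#' @param n_early,n_late Group sizes (onset-to-MRI time <= 4.5 h, > 4.5 h).
#' @param time_early,time_late Onset-time law per group: list with `median`,
#'   `q1`, `q3` in hours; sampled from a log-normal matched to these
#'   quartiles, truncated to the group's side of `cutoff_h` and capped at
#'   `time_cap_h`.
#' @param cutoff_h Onset-window cutoff in hours.
#' @param time_cap_h Inclusion cap on onset-to-MRI time, hours.
#' @param prevalence Named list; each element is `c(early, late)` prevalence
#'   of a binary covariate.
#' @param sir_beta0,sir_beta1,sir_beta2,sir_sigma SIR model coefficients:
#'   intercept, log-time slope (per log-hour), LVO shift, residual SD
#'   (all dimensionless SIR units).
#' @param mismatch_threshold SIR below which the DWI-FLAIR mismatch
#'   surrogate is positive.
#' @param age,nihss,dwi_volume,pwi_dwi Per-group quartile targets
#'   (`list(early = c(med, q1, q3), late = ...)`) for the remaining
#'   continuous covariates. NIHSS is rounded and clipped to 0--42; age is
#'   rounded and clipped to 27--94 years.
#' @param seed Integer seed; identical configs generate identical cohorts.
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [summarize_cohort()]
#' @export
cohort_config <- function(n_early = 358L,
                          n_late = 275L,
                          time_early = list(median = 3.5, q1 = 1.5, q3 = 4),
                          time_late = list(median = 7.5, q1 = 6, q3 = 12),
                          cutoff_h = 4.5,
                          time_cap_h = 24,
                          prevalence = list(
                            sex_male            = c(0.651, 0.698),
                            hypertension        = c(0.768, 0.800),
                            diabetes            = c(0.310, 0.360),
                            hyperlipemia        = c(0.092, 0.356),
                            smoking             = c(0.279, 0.233),
                            drinking            = c(0.190, 0.167),
                            atrial_fibrillation = c(0.293, 0.247),
                            lvo                 = c(0.310, 0.644)
                          ),
                          sir_beta0 = 0.984,
                          sir_beta1 = 0.065,
                          sir_beta2 = 0.075,
                          sir_sigma = 0.065,
                          mismatch_threshold = 1.115,
                          age = list(early = c(71, 62, 79), late = c(69, 59, 78)),
                          nihss = list(early = c(8, 3, 13), late = c(9, 4, 13)),
                          dwi_volume = list(early = c(14, 5, 28), late = c(17, 5, 31)),
                          pwi_dwi = list(early = c(2.0742, 1.2333, 5.6396),
                                         late = c(2.5051, 1.8, 6.2495)),
                          seed = 1L) {
  cfg <- list(
    n_early = as.integer(n_early), n_late = as.integer(n_late),
    time_early = time_early, time_late = time_late,
    cutoff_h = cutoff_h, time_cap_h = time_cap_h,
    prevalence = prevalence,
    sir_beta0 = sir_beta0, sir_beta1 = sir_beta1,
    sir_beta2 = sir_beta2, sir_sigma = sir_sigma,
    mismatch_threshold = mismatch_threshold,
    age = age, nihss = nihss, dwi_volume = dwi_volume, pwi_dwi = pwi_dwi,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_early < 0 || cfg$n_late < 0) {
    abort("group sizes must be non-negative", class = "flairsir_config_error")
  }
  betas <- c(cfg$sir_beta0, cfg$sir_beta1, cfg$sir_beta2, cfg$sir_sigma)
  if (any(!is.finite(betas))) {
    abort("SIR model coefficients must be finite", class = "flairsir_config_error")
  }
  if (cfg$sir_sigma < 0) {
    abort("sir_sigma must be >= 0", class = "flairsir_config_error")
  }
  prev <- unlist(cfg$prevalence)
  if (any(prev < 0 | prev > 1)) {
    abort("prevalences must lie in [0, 1]", class = "flairsir_config_error")
  }
  invisible(cfg)
}

# continuous covariate from per-group quartile targets; least-squares fit
# over all three quantiles (log-quartiles of skewed covariates like NIHSS
# are asymmetric, which a moment match would ignore)
sample_quartile_lnorm <- function(n, target) {
  p <- lnorm_trunc_fit(target[1], target[2], target[3], 0, Inf)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

generate_group <- function(n, group, cfg) {
  if (n == 0L) return(empty_cohort())
  tl <- if (group == "early") cfg$time_early else cfg$time_late
  lim <- if (group == "early") c(0, cfg$cutoff_h) else c(cfg$cutoff_h, cfg$time_cap_h)
  # fit so the truncated law itself has the target quartiles
  tp <- lnorm_trunc_fit(tl$median, tl$q1, tl$q3, lim[1], lim[2])
  t_h <- rlnorm_trunc(n, tp$meanlog, tp$sdlog, lower = lim[1], upper = lim[2])

  gi <- if (group == "early") 1L else 2L
  covs <- purrr::map(cfg$prevalence, ~ rbinom(n, 1L, .x[gi]) == 1L)

  agep <- cfg$age[[group]]
  age <- round(rnorm_trunc(n, agep[1], (agep[3] - agep[2]) / (2 * qnorm(0.75)),
                           lower = 27, upper = 94))
  nih <- cfg$nihss[[group]]
  nihss <- pmin(42L, pmax(0L, as.integer(round(
    sample_quartile_lnorm(n, nih)))))
  dwi_ml <- sample_quartile_lnorm(n, cfg$dwi_volume[[group]])
  pwi <- sample_quartile_lnorm(n, cfg$pwi_dwi[[group]])

  sir <- cfg$sir_beta0 + cfg$sir_beta1 * log1p(t_h) +
    cfg$sir_beta2 * as.numeric(covs$lvo) + rnorm(n, 0, cfg$sir_sigma)
  sir <- pmax(sir, 1.0)

  tibble(
    id = NA_character_,
    onset_to_mri_h = t_h,
    sex_male = covs$sex_male,
    age_y = as.numeric(age),
    nihss = nihss,
    hypertension = covs$hypertension,
    diabetes = covs$diabetes,
    hyperlipemia = covs$hyperlipemia,
    smoking = covs$smoking,
    drinking = covs$drinking,
    atrial_fibrillation = covs$atrial_fibrillation,
    lvo = covs$lvo,
    pwi_dwi_mismatch = pwi,
    dwi_volume_ml = dwi_ml,
    sir = sir,
    dwi_flair_mismatch = sir < cfg$mismatch_threshold,
    late = t_h > cfg$cutoff_h
  )
}

empty_cohort <- function() {
  tibble(
    id = character(), onset_to_mri_h = numeric(), sex_male = logical(),
    age_y = numeric(), nihss = integer(), hypertension = logical(),
    diabetes = logical(), hyperlipemia = logical(), smoking = logical(),
    drinking = logical(), atrial_fibrillation = logical(), lvo = logical(),
    pwi_dwi_mismatch = numeric(), dwi_volume_ml = numeric(), sir = numeric(),
    dwi_flair_mismatch = logical(), late = logical()
  )
}

#' Generate a synthetic stroke cohort
#'
#' Draws one patient-level table from the generative model described in
#' [cohort_config()]. Onset times are sampled per group from truncated
#' log-normals straddling the 4.5 h cutoff; binary covariates are drawn
#' independently at their per-group prevalences; SIR follows the censored
#' linear model in log lesion age and LVO.
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of `config$seed`.
#' @return A tibble with one row per patient and the columns of the
#'   `PatientRecord` layout (`id`, `onset_to_mri_h`, binary risk factors,
#'   `lvo`, `pwi_dwi_mismatch`, `dwi_volume_ml`, `sir`,
#'   `dwi_flair_mismatch`, `late`).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' dplyr::count(cohort, late)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  seed <- seed %||% config$seed
  with_seed(seed, {
    out <- dplyr::bind_rows(
      generate_group(config$n_early, "early", config),
      generate_group(config$n_late, "late", config)
    )
    if (nrow(out)) out$id <- sprintf("P%04d", seq_len(nrow(out)))
    out
  })
}

#' Per-group cohort summary with two-sample tests
#'
#' Summarises each cohort variable per onset-window group: continuous
#' variables as median (IQR) with a Mann-Whitney U p-value, binary
#' variables as n (%) with a Pearson chi-squared p-value (no continuity
#' correction), matching standard baseline-characteristics tables.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or any table
#'   with a logical `late` column).
#' @param group Name of the logical grouping column, default `"late"`.
#' @return A tibble with columns `variable`, `kind`, per-group numeric
#'   summaries (`*_early`, `*_late`), formatted `early`/`late` labels and
#'   `p_value`. Variables with an empty group are flagged via `NA`
#'   summaries rather than an error.
#' @export
summarize_cohort <- function(cohort, group = "late") {
  stopifnot(group %in% names(cohort))
  g <- cohort[[group]]
  vars <- setdiff(names(cohort), c("id", group))
  rows <- purrr::map(vars, function(v) {
    x <- cohort[[v]]
    xe <- x[!g]
    xl <- x[g]
    if (is.logical(x)) {
      summarize_binary(v, xe, xl)
    } else {
      summarize_continuous(v, xe, xl)
    }
  })
  dplyr::bind_rows(rows)
}

summarize_binary <- function(v, xe, xl) {
  ne <- length(xe); nl <- length(xl)
  pe <- if (ne) 100 * mean(xe) else NA_real_
  pl <- if (nl) 100 * mean(xl) else NA_real_
  p <- if (ne && nl && !all(c(xe, xl)) && any(c(xe, xl))) {
    chi_square(build_two_by_two(c(xe, xl), c(rep(FALSE, ne), rep(TRUE, nl))))$p_value
  } else if (ne && nl) {
    1 # degenerate margin: identical constant proportions
  } else {
    NA_real_
  }
  tibble(
    variable = v, kind = "binary",
    n_early = sum(xe), pct_early = pe, n_late = sum(xl), pct_late = pl,
    median_early = NA_real_, q1_early = NA_real_, q3_early = NA_real_,
    median_late = NA_real_, q1_late = NA_real_, q3_late = NA_real_,
    early = if (ne) sprintf("%d (%.1f%%)", sum(xe), pe) else NA_character_,
    late = if (nl) sprintf("%d (%.1f%%)", sum(xl), pl) else NA_character_,
    p_value = p
  )
}

summarize_continuous <- function(v, xe, xl) {
  qe <- if (length(xe)) quantile(xe, c(0.5, 0.25, 0.75), names = FALSE) else rep(NA_real_, 3)
  ql <- if (length(xl)) quantile(xl, c(0.5, 0.25, 0.75), names = FALSE) else rep(NA_real_, 3)
  p <- if (length(xe) && length(xl)) mann_whitney(xl, xe)$p_value else NA_real_
  tibble(
    variable = v, kind = "continuous",
    n_early = NA_integer_, pct_early = NA_real_,
    n_late = NA_integer_, pct_late = NA_real_,
    median_early = qe[1], q1_early = qe[2], q3_early = qe[3],
    median_late = ql[1], q1_late = ql[2], q3_late = ql[3],
    early = if (length(xe)) sprintf("%.2f (%.2f, %.2f)", qe[1], qe[2], qe[3]) else NA_character_,
    late = if (length(xl)) sprintf("%.2f (%.2f, %.2f)", ql[1], ql[2], ql[3]) else NA_character_,
    p_value = p
  )
}

#' Write a cohort to CSV with its configuration
#'
#' Booleans are written as 0/1 and times in hours; the configuration is
#' saved as YAML next to the CSV so a run can be reproduced exactly.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @param config Optional [cohort_config()] written to
#'   `<path>.config.yaml`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  out <- dplyr::mutate(cohort, dplyr::across(dplyr::where(is.logical), as.integer))
  readr::write_csv(out, path)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), paste0(path, ".config.yaml"))
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @return Cohort tibble with logical columns restored.
#' @export
read_cohort <- function(path) {
  bool_cols <- c("sex_male", "hypertension", "diabetes", "hyperlipemia",
                 "smoking", "drinking", "atrial_fibrillation", "lvo",
                 "dwi_flair_mismatch", "late")
  x <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::mutate(x, dplyr::across(dplyr::any_of(bool_cols), ~ .x == 1))
}
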