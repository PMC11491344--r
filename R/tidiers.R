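# broom-style tidiers for the package's fitted objects

#' Tidy a logistic fit
#' @param x A `sir_logit`.
#' @param ... Unused.
#' @return Per-term tibble with estimates, SEs, ORs, Wald CIs, p-values.
#' @exportS3Method generics::tidy
tidy.sir_logit <- function(x, ...) x$coefficients

#' @rdname tidy.sir_logit
#' @exportS3Method generics::glance
glance.sir_logit <- function(x, ...) {
  tibble(n = x$n, log_lik = x$log_lik, deviance = x$deviance,
         null_deviance = x$null_deviance, n_iter = x$n_iter,
         converged = x$converged, status = x$status)
}

#' Tidy a ROC curve: its stepwise coordinates
#' @param x A `sir_roc`.
#' @param ... Unused.
#' @return Tibble of `threshold`, `tpr`, `fpr`.
#' @exportS3Method generics::tidy
tidy.sir_roc <- function(x, ...) {
  tibble(threshold = x$thresholds, tpr = x$tpr, fpr = x$fpr)
}

#' @rdname tidy.sir_roc
#' @exportS3Method generics::glance
glance.sir_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_variance = x$auc_variance,
         n_late = x$n1, n_early = x$n0)
}

#' Tidy a hierarchical block regression: per-block model statistics
#' @param x A `sir_blocks`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sir_blocks <- function(x, ...) x$summary

#' Tidy a mediation result: effect estimates with CIs
#' @param x A `sir_mediation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sir_mediation <- function(x, ...) x$estimates

#' @rdname tidy.sir_mediation
#' @exportS3Method generics::glance
glance.sir_mediation <- function(x, ...) {
  tibble(method = x$method, n_sims = x$n_sims,
         treat_control = x$treat_values[1], treat_treated = x$treat_values[2],
         total_ci_excludes_zero = x$total_ci_excludes_zero)
}
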