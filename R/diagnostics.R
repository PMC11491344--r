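#' Build a 2x2 contingency table for onset-window diagnostics
#'
#' Orientation is fixed throughout the package: the positive outcome class
#' is a late onset window (> 4.5 h), so `a` counts predictor-positive late
#' patients, `b` predictor-negative late, `c` predictor-positive early and
#' `d` predictor-negative early.
#'
#' @param predictor Logical vector (or 0/1) of predictor positivity.
#' @param late Logical vector (or 0/1), `TRUE` when onset > 4.5 h.
#' @return An object of class `two_by_two` with fields `a`, `b`, `c`, `d`.
#' @examples
#' build_two_by_two(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
#' @export
build_two_by_two <- function(predictor, late) {
  predictor <- as.logical(predictor)
  late <- as.logical(late)
  if (length(predictor) != length(late)) {
    abort("predictor and outcome must have equal length",
          class = "flairsir_input_error")
  }
  if (length(predictor) < 1L) {
    abort("need at least one observation", class = "flairsir_input_error")
  }
  structure(
    list(a = sum(predictor & late), b = sum(!predictor & late),
         c = sum(predictor & !late), d = sum(!predictor & !late)),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(predictor = c("+", "-"),
                              outcome = c("late", "early")))
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(t) matrix(c(t$a, t$b, t$c, t$d), 2)

#' Diagnostic metrics of a binary predictor
#'
#' Sensitivity `a/(a+b)`, specificity `d/(c+d)`, PPV `a/(a+c)`,
#' NPV `d/(b+d)`, accuracy `(a+d)/n` and, for a binary predictor, the
#' ROC area `(sensitivity + specificity)/2`. Metrics with a zero
#' denominator are returned as `NA` rather than raising an error.
#'
#' @param t A [build_two_by_two()] table.
#' @param cutoff Operating threshold recorded alongside the metrics
#'   (0.5 by convention for a binary predictor).
#' @return One-row tibble with the metrics above.
#' @export
diagnostic_metrics <- function(t, cutoff = 0.5) {
  stopifnot(inherits(t, "two_by_two"))
  n <- t$a + t$b + t$c + t$d
  if (n == 0L) abort("empty table", class = "flairsir_input_error")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(t$a, t$a + t$b)
  spec <- safe_div(t$d, t$c + t$d)
  tibble(
    cutoff = cutoff,
    accuracy = (t$a + t$d) / n,
    sensitivity = sens,
    specificity = spec,
    ppv = safe_div(t$a, t$a + t$c),
    npv = safe_div(t$d, t$b + t$d),
    auc = (sens + spec) / 2
  )
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = (a d)/(b c)` with 95% CI `exp(log OR +- z * sqrt(1/a + 1/b +
#' 1/c + 1/d))` and a two-sided Wald p-value. With
#' `correction = "haldane"` 0.5 is added to every cell, allowing zero
#' cells.
#'
#' @param t A [build_two_by_two()] table.
#' @param correction `"none"` (error on zero cells) or `"haldane"`.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratio <- function(t, correction = c("none", "haldane"),
                       conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  correction <- match.arg(correction)
  cells <- c(t$a, t$b, t$c, t$d)
  if (correction == "haldane") {
    cells <- cells + 0.5
  } else if (any(cells == 0)) {
    abort("zero cell; use correction = \"haldane\"",
          class = "flairsir_input_error")
  }
  lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    or = exp(lor),
    ci_low = exp(lor - z * se),
    ci_high = exp(lor + z * se),
    p_value = 2 * pnorm(-abs(lor / se))
  )
}

#' Empirical ROC curve with DeLong variance
#'
#' Computes the empirical ROC of a score for discriminating late
#' (> 4.5 h) from early onset, the trapezoidal AUC (equal to the
#' tie-corrected Mann-Whitney statistic U/(n1 n0)), and the DeLong
#' structural components from which the AUC variance and paired-curve
#' covariance are derived.
#'
#' @param scores Numeric scores; larger values indicate late onset.
#' @param late Logical outcome vector.
#' @return Object of class `sir_roc`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `auc_variance`, structural components `v10` (per late subject),
#'   `v01` (per early subject), and the label vector (for pairing checks).
#' @export
roc_curve <- function(scores, late) {
  late <- as.logical(late)
  if (length(scores) != length(late)) {
    abort("scores and labels must have equal length",
          class = "flairsir_input_error")
  }
  if (anyNA(scores) || anyNA(late)) {
    abort("missing values in scores or labels", class = "flairsir_input_error")
  }
  n1 <- sum(late); n0 <- sum(!late)
  if (n1 == 0L || n0 == 0L) {
    abort("both outcome classes must be present", class = "flairsir_input_error")
  }
  x1 <- scores[late]
  x0 <- scores[!late]

  # Mann-Whitney kernel via midranks: psi = 1, 1/2, 0 for >, =, <
  r_all <- rank(c(x1, x0))
  r1 <- rank(x1)
  r0 <- rank(x0)
  v10 <- (r_all[seq_len(n1)] - r1) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r0) / n1
  auc <- mean(v10)

  s10 <- if (n1 > 1) var(v10) else 0
  s01 <- if (n0 > 1) var(v01) else 0

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(x1 >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(x0 >= s), numeric(1))

  structure(
    list(thresholds = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr),
         auc = auc, auc_variance = s10 / n1 + s01 / n0,
         v10 = v10, v01 = v01, late = late, scores = scores,
         n1 = n1, n0 = n0),
    class = "sir_roc"
  )
}

#' @export
print.sir_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d late / %d early, AUC = %.3f (DeLong SE %.4f)\n",
              x$n1, x$n0, x$auc, sqrt(x$auc_variance)))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Scans candidate thresholds at midpoints between consecutive unique
#' score values (plus outer sentinels) and returns the threshold
#' maximising Youden's J = sensitivity + specificity - 1, breaking ties
#' toward the lower threshold. The classification rule is
#' `score > threshold`; for a 0/1 predictor this yields the conventional
#' cutoff 0.5.
#'
#' @param roc A [roc_curve()] object.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "sir_roc"))
  u <- sort(unique(roc$scores))
  cand <- if (length(u) == 1L) {
    u
  } else {
    c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1)
  }
  x1 <- roc$scores[roc$late]
  x0 <- roc$scores[!roc$late]
  sens <- vapply(cand, function(s) mean(x1 > s), numeric(1))
  spec <- vapply(cand, function(s) mean(x0 <= s), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1] # candidates ascend; first max = lowest threshold
  tibble(threshold = cand[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best])
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two ROC curves built on the same subjects (same outcome
#' labels, row order preserved) using the DeLong structural-component
#' estimator of the variance of the AUC difference:
#' `z = (auc1 - auc2) / sqrt(var1 + var2 - 2 cov)`.
#'
#' @param roc1,roc2 [roc_curve()] objects on the same subjects.
#' @return One-row tibble: `auc1`, `auc2`, `z`, `p_value`. A degenerate
#'   variance (e.g. a curve compared with itself) yields `z = 0`,
#'   `p = 1`.
#' @export
delong_paired_test <- function(roc1, roc2) {
  stopifnot(inherits(roc1, "sir_roc"), inherits(roc2, "sir_roc"))
  if (roc1$n1 != roc2$n1 || roc1$n0 != roc2$n0 ||
      !identical(roc1$late, roc2$late)) {
    abort("curves must be built on the same subjects and labels",
          class = "flairsir_input_error")
  }
  v1 <- roc1$auc_variance
  v2 <- roc2$auc_variance
  cv <- cov(roc1$v10, roc2$v10) / roc1$n1 + cov(roc1$v01, roc2$v01) / roc1$n0
  dvar <- v1 + v2 - 2 * cv
  if (!is.finite(dvar) || dvar <= .Machine$double.eps) {
    z <- 0
  } else {
    z <- (roc1$auc - roc2$auc) / sqrt(dvar)
  }
  tibble(auc1 = roc1$auc, auc2 = roc2$auc, z = z,
         p_value = if (z == 0) 1 else 2 * pnorm(-abs(z)))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; p-value from `t = rho sqrt((n-2)/(1-rho^2))`
#' on n - 2 degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return One-row tibble: `rho`, `statistic`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs", class = "flairsir_input_error")
  if (min(x) == max(x) || min(y) == max(y)) {
    abort("constant vector", class = "flairsir_input_error")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(tibble(rho = rho, statistic = Inf * sign(rho), p_value = 0, n = n))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  tibble(rho = rho, statistic = tstat,
         p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction by default, matching the group-comparison
#' convention used for baseline tables; Yates correction available.
#'
#' @param t A [build_two_by_two()] table.
#' @param correct Apply Yates continuity correction.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_square <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  m <- as_matrix_2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("empty margin", class = "flairsir_input_error")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Mann-Whitney U test
#'
#' U statistic of `x` against `y` with normal approximation and tie
#' correction (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (U for `x`), `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    abort("both samples must be non-empty", class = "flairsir_input_error")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1 # all values tied: zero variance, no evidence
  list(statistic = unname(wt$statistic), p_value = p)
}
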