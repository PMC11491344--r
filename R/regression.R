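#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary outcome on a set of
#' predictor columns, with Wald standard errors from the inverse observed
#' information, odds ratios `exp(coef)` and Wald 95% CIs. Step-halving
#' guarantees the log-likelihood is non-decreasing across iterations.
#' Complete or quasi-complete separation is flagged (`converged = FALSE`,
#' `status = "separation"`) and the last iterate is returned with a
#' warning rather than an error.
#'
#' @param data Data frame; logical predictors are coerced to 0/1.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor column names.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the log-likelihood improvement
#'   (iteration also stops when the coefficient step falls below 1e-8).
#' @return Object of class `sir_logit` with elements `coefficients`
#'   (tibble: `term`, `estimate`, `std_error`, `or`, `ci_low`, `ci_high`,
#'   `p_value`), `vcov`, `log_lik`, `log_lik_trace`, `null_deviance`,
#'   `deviance`, `n`, `n_iter`, `converged`, `status`, plus the terms
#'   needed by [risk_score()].
#' @examples
#' d <- generate_cohort(cohort_config(seed = 7))
#' fit <- fit_logistic(d, "late", c("hyperlipemia", "lvo"))
#' tidy(fit)
#' @export
fit_logistic <- function(data, outcome, predictors,
                         max_iter = 100L, tol = 1e-10) {
  y <- as.numeric(data[[outcome]])
  if (anyNA(y) || !is_binary01(y)) {
    abort("outcome must be binary 0/1", class = "flairsir_input_error")
  }
  X <- build_design(data, predictors)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort("need n > number of parameters", class = "flairsir_input_error")
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("degenerate design: constant column(s) ",
                 paste(names(sds)[sds == 0], collapse = ", ")),
          class = "flairsir_design_error")
  }

  beta <- numeric(p)
  ll <- logit_loglik(X, y, beta)
  trace <- ll
  status <- "ok"
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { status <- "singular_information"; break }
    # step-halving: enforce likelihood ascent
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- logit_loglik(X, y, beta_new)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    delta_ll <- ll_new - ll
    beta <- beta_new
    ll <- max(ll, ll_new)
    trace <- c(trace, ll)
    # converge on the coefficient step and the likelihood improvement,
    # which are invariant to the scale of the predictors
    if (max(abs(lambda * step)) < 1e-8 || abs(delta_ll) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  # separation heuristic: fitted probabilities at machine bounds with
  # runaway coefficients
  ext <- mu < 1e-8 | mu > 1 - 1e-8
  if (any(abs(beta) > 15) && any(ext) && all(abs(y - mu)[ext] < 1e-6)) {
    status <- "separation"
    converged <- FALSE
    warn("possible complete separation; coefficients unreliable")
  }
  if (!converged && status == "ok") {
    status <- "max_iter"
    warn("IRLS did not converge within max_iter")
  }

  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * w, X)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vc))
  zq <- qnorm(0.975)
  beta <- unname(beta)
  se <- unname(se)
  coefs <- tibble(
    term = colnames(X),
    estimate = beta,
    std_error = se,
    or = exp(beta),
    ci_low = exp(beta - zq * se),
    ci_high = exp(beta + zq * se),
    p_value = 2 * pnorm(-abs(beta / se))
  )
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = coefs, vcov = vc,
         log_lik = ll, log_lik_trace = trace,
         deviance = -2 * ll,
         null_deviance = -2 * logit_loglik(matrix(1, n, 1), y,
                                           qlogis(max(min(mean(y), 1 - 1e-12), 1e-12))),
         n = n, n_iter = it, converged = converged, status = status,
         outcome = outcome, predictors = predictors),
    class = "sir_logit"
  )
}

build_design <- function(data, predictors) {
  if (!length(predictors)) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  missing <- setdiff(predictors, names(data))
  if (length(missing)) {
    abort(paste("unknown predictor(s):", paste(missing, collapse = ", ")),
          class = "flairsir_input_error")
  }
  cols <- purrr::map(predictors, ~ as.numeric(data[[.x]]))
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", predictors)
  if (anyNA(X)) abort("missing values in predictors", class = "flairsir_input_error")
  X
}

logit_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' @export
print.sir_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s ~ %s), n = %d, logLik = %.3f%s\n",
              x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
              x$n, x$log_lik,
              if (x$converged) "" else paste0(" [", x$status, "]")))
  print(x$coefficients)
  invisible(x)
}

#' Backward stepwise selection for the multivariable onset-window model
#'
#' Candidates are first screened univariately (entry when the Wald p-value
#' is below `p_enter`); the joint model is then reduced by backward
#' elimination, repeatedly dropping the predictor with the largest Wald
#' p >= `p_remove` until all remaining predictors are significant. The
#' procedure is deterministic given the data.
#'
#' @param data Data frame.
#' @param outcome Binary outcome column name.
#' @param candidates Character vector of candidate predictors.
#' @param p_enter Univariate screening threshold.
#' @param p_remove Backward elimination threshold.
#' @return A `sir_logit` fit on the selected predictors with attributes
#'   `selected` (character vector) and `univariate` (screening tibble).
#'   An empty candidate or selection set yields the intercept-only model.
#' @export
stepwise_select <- function(data, outcome, candidates,
                            p_enter = 0.05, p_remove = 0.05) {
  uni <- purrr::map_dfr(candidates, function(v) {
    fit <- fit_logistic(data, outcome, v)
    dplyr::mutate(fit$coefficients[2, ], term = v)
  })
  keep <- if (length(candidates)) uni$term[uni$p_value < p_enter] else character()
  current <- keep
  repeat {
    fit <- fit_logistic(data, outcome, current)
    if (!length(current)) break
    pv <- fit$coefficients$p_value[-1]
    worst <- which.max(pv)
    if (pv[worst] < p_remove) break
    current <- current[-worst]
  }
  attr(fit, "selected") <- current
  attr(fit, "univariate") <- uni
  fit
}

#' Hierarchical block regression with R-squared-change F tests
#'
#' Fits nested cumulative models over ordered predictor blocks and
#' reports, per block, coefficients with SEs, R-squared, adjusted
#' R-squared, the overall F test, the R-squared change against the
#' previous block and the F-change test
#' `F = ((R2_full - R2_reduced)/q) / ((1 - R2_full)/(n - k - 1))`.
#' The default model family is ordinary least squares on the 0/1 outcome
#' (a linear probability model, whose B, SE, R-squared and F quantities
#' match standard stratified-regression tables); a logistic family is
#' available, reporting McFadden pseudo-R-squared and likelihood-ratio
#' chi-squared change instead.
#'
#' @param data Data frame.
#' @param outcome Binary (0/1 or logical) outcome column name.
#' @param blocks Ordered list of character vectors; block k is added to
#'   all previous blocks. A column duplicating one already in the model
#'   is dropped (rank deficiency) with a warning and contributes zero
#'   R-squared change.
#' @param family `"lpm"` (OLS on 0/1 outcome) or `"logistic"`.
#' @return Object of class `sir_blocks`: `summary` tibble (one row per
#'   block: `block`, `r_squared`, `adj_r_squared`, `f_value`, `df1`,
#'   `df2`, `p_value`, `delta_r_squared`, `f_change`, `df1_change`,
#'   `df2_change`, `p_change`) and `coefficients` (list of per-block
#'   tibbles with `term`, `estimate`, `std_error`, `p_value`).
#' @export
hierarchical_blocks <- function(data, outcome, blocks,
                                family = c("lpm", "logistic")) {
  family <- match.arg(family)
  y <- as.numeric(data[[outcome]])
  if (family == "lpm") {
    hierarchical_blocks_lpm(data, y, blocks)
  } else {
    hierarchical_blocks_logit(data, outcome, blocks)
  }
}

hierarchical_blocks_lpm <- function(data, y, blocks) {
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  cum <- character()
  prev_r2 <- 0
  prev_rank <- 0L
  rows <- list(); coefs <- list()
  for (k in seq_along(blocks)) {
    cum <- c(cum, blocks[[k]])
    X <- build_design(data, cum)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
      warn(paste("rank-deficient design; dropping:",
                 paste(dropped, collapse = ", ")))
      X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
      qr_x <- qr(X)
    }
    kk <- ncol(X) - 1L # predictors excluding intercept
    beta <- qr.coef(qr_x, y)
    res <- y - drop(X %*% beta)
    sse <- sum(res^2)
    r2 <- 1 - sse / sst
    df2 <- n - kk - 1L
    sigma2 <- sse / df2
    xtx_inv <- solve(crossprod(X))
    se <- sqrt(diag(xtx_inv) * sigma2)
    f_overall <- if (kk > 0) (r2 / kk) / ((1 - r2) / df2) else NA_real_
    q <- kk - prev_rank
    dr2 <- r2 - prev_r2
    if (q > 0) {
      f_change <- (dr2 / q) / ((1 - r2) / df2)
      p_change <- pf(f_change, q, df2, lower.tail = FALSE)
    } else {
      f_change <- 0
      p_change <- 1
    }
    beta <- unname(beta)
    se <- unname(se)
    rows[[k]] <- tibble(
      block = k, r_squared = r2,
      adj_r_squared = 1 - (1 - r2) * (n - 1) / df2,
      f_value = f_overall, df1 = kk, df2 = df2,
      p_value = if (kk > 0) pf(f_overall, kk, df2, lower.tail = FALSE) else NA_real_,
      delta_r_squared = dr2, f_change = f_change,
      df1_change = q, df2_change = df2, p_change = p_change
    )
    coefs[[k]] <- tibble(
      term = colnames(X), estimate = beta, std_error = se,
      p_value = 2 * pt(-abs(beta / se), df2)
    )
    prev_r2 <- r2
    prev_rank <- kk
  }
  structure(list(summary = dplyr::bind_rows(rows), coefficients = coefs,
                 family = "lpm", n = n),
            class = "sir_blocks")
}

hierarchical_blocks_logit <- function(data, outcome, blocks) {
  cum <- character()
  prev_dev <- NULL
  prev_k <- 0L
  rows <- list(); coefs <- list()
  null_dev <- NULL
  for (k in seq_along(blocks)) {
    new <- setdiff(blocks[[k]], cum)
    cum <- c(cum, new)
    fit <- fit_logistic(data, outcome, cum)
    if (is.null(null_dev)) null_dev <- fit$null_deviance
    r2 <- 1 - fit$deviance / null_dev # McFadden
    q <- length(cum) - prev_k
    dchi <- if (is.null(prev_dev)) null_dev - fit$deviance else prev_dev - fit$deviance
    rows[[k]] <- tibble(
      block = k, r_squared = r2,
      adj_r_squared = NA_real_,
      f_value = NA_real_, df1 = length(cum), df2 = NA_integer_,
      p_value = NA_real_,
      delta_r_squared = if (is.null(prev_dev)) r2 else r2 - (1 - prev_dev / null_dev),
      f_change = dchi, df1_change = q, df2_change = NA_integer_,
      p_change = if (q > 0) pchisq(dchi, q, lower.tail = FALSE) else 1
    )
    coefs[[k]] <- fit$coefficients
    prev_dev <- fit$deviance
    prev_k <- length(cum)
  }
  structure(list(summary = dplyr::bind_rows(rows), coefficients = coefs,
                 family = "logistic", n = nrow(data)),
            class = "sir_blocks")
}

#' @export
print.sir_blocks <- function(x, ...) {
  cat(sprintf("Hierarchical block regression (%s family), n = %d\n",
              x$family, x$n))
  print(x$summary)
  invisible(x)
}

#' Per-subject risk score from a fitted logistic model
#'
#' Evaluates the linear predictor and predicted probability of a late
#' onset window for each row of `data`. Rows with missing covariates are
#' excluded and reported via the `n_dropped` attribute and a message.
#'
#' @param fit A `sir_logit` from [fit_logistic()] or [stepwise_select()].
#' @param data Data frame containing the model's predictor columns.
#' @return Tibble with `.row`, `linear_predictor`, `probability`.
#' @export
risk_score <- function(fit, data) {
  stopifnot(inherits(fit, "sir_logit"))
  preds <- fit$predictors
  cols <- purrr::map(preds, ~ as.numeric(data[[.x]]))
  X <- cbind(1, if (length(cols)) do.call(cbind, cols))
  ok <- stats::complete.cases(X)
  if (any(!ok)) {
    message(sum(!ok), " row(s) with missing covariates excluded")
  }
  eta <- drop(X[ok, , drop = FALSE] %*% fit$coefficients$estimate)
  out <- tibble(.row = which(ok), linear_predictor = eta,
                probability = plogis(eta))
  attr(out, "n_dropped") <- sum(!ok)
  out
}
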