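test_that("univariate logistic OR on a binary predictor equals the 2x2 OR", {
  counts <- table1_counts()
  e <- counts_to_vectors(111, counts$n_early, 177, counts$n_late)
  d <- tibble::tibble(lvo = e$predictor, late = e$late)
  fit <- fit_logistic(d, "late", "lvo")
  expect_true(fit$converged)
  expect_equal(round(fit$coefficients$or[2], 3), 4.019)

  # identity holds on arbitrary random tables to 1e-8
  set.seed(8)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    p <- runif(n) > runif(1, 0.3, 0.7)
    l <- (runif(n) + 0.3 * p) > 0.5
    t <- build_two_by_two(p, l)
    if (min(t$a, t$b, t$c, t$d) == 0) next
    f <- fit_logistic(tibble::tibble(p = p, l = l), "l", "p")
    expect_equal(f$coefficients$or[2], odds_ratio(t)$or, tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected", {
  d <- tibble::tibble(x = rep(0, 20), late = rep(c(TRUE, FALSE), 10))
  expect_error(fit_logistic(d, "late", "x"), class = "flairsir_design_error")
  expect_error(fit_logistic(d[1, ], "late", "x"), class = "flairsir_input_error")
  d2 <- tibble::tibble(x = rnorm(10), y = rep(2, 10))
  expect_error(fit_logistic(d2, "y", "x"), class = "flairsir_input_error")
})

test_that("complete separation is flagged, not silently reported", {
  d <- tibble::tibble(x = c(1:5, 11:15), late = rep(c(FALSE, TRUE), each = 5))
  expect_warning(fit <- fit_logistic(d, "late", "x"))
  expect_false(fit$converged)
  expect_equal(fit$status, "separation")
})

test_that("the IRLS maximum matches a coarse-to-fine grid search on a toy fit", {
  d <- tibble::tibble(
    x = c(0.1, 0.4, 0.5, 0.9, 1.1, 1.4, 1.7, 2.0, 2.3, 2.6, 2.9, 3.2),
    late = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
             TRUE, TRUE, TRUE)
  )
  fit <- fit_logistic(d, "late", "x")

  ll <- function(b0, b1) {
    eta <- b0 + b1 * d$x
    sum(as.numeric(d$late) * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0); width <- 8
  for (level in 1:6) {
    g0 <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    g1 <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    grid <- expand.grid(b0 = g0, b1 = g1)
    vals <- mapply(ll, grid$b0, grid$b1)
    centre <- unlist(grid[which.max(vals), ])
    width <- width / 8
  }
  expect_equal(fit$log_lik, max(vals), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$estimate), unname(centre),
               tolerance = 1e-3)
})

test_that("IRLS log-likelihood is non-decreasing and matches glm", {
  co <- generate_cohort(small_config(seed = 6))
  fit <- fit_logistic(co, "late", c("hyperlipemia", "lvo", "sir"))
  expect_true(all(diff(fit$log_lik_trace) >= -1e-10))

  ref <- stats::glm(late ~ hyperlipemia + lvo + sir, data = co,
                    family = stats::binomial())
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$std_error),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(fit$log_lik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
})

test_that("backward stepwise keeps the three generative signals on the default cohort", {
  co <- generate_cohort(cohort_config(seed = 1))
  co$sir_rescaled <- co$sir * 100
  cand <- c("sex_male", "age_y", "nihss", "hypertension", "diabetes",
            "hyperlipemia", "smoking", "drinking", "atrial_fibrillation",
            "pwi_dwi_mismatch", "lvo", "sir_rescaled")
  sel <- stepwise_select(co, "late", cand)
  expect_setequal(attr(sel, "selected"), c("hyperlipemia", "lvo", "sir_rescaled"))
  expect_true(all(tidy(sel)$p_value[-1] < 0.05))
})

test_that("a single strong predictor among noise survives selection", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 300
    x <- rnorm(n)
    noise <- matrix(rnorm(n * 4), n, 4)
    d <- tibble::tibble(x = x, n1 = noise[, 1], n2 = noise[, 2],
                        n3 = noise[, 3], n4 = noise[, 4],
                        late = plogis(1.2 * x) > runif(n))
    sel <- attr(stepwise_select(d, "late", c("x", "n1", "n2", "n3", "n4")),
                "selected")
    if ("x" %in% sel) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("pure-noise candidates are almost always pruned to <= 1 predictor", {
  small_sel <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 600
    d <- tibble::as_tibble(matrix(rnorm(n * 5), n, 5),
                           .name_repair = ~ paste0("z", 1:5))
    d$late <- runif(n) > 0.5
    sel <- attr(stepwise_select(d, "late", paste0("z", 1:5)), "selected")
    if (length(sel) <= 1) small_sel <- small_sel + 1
  }
  expect_gte(small_sel, 18)
})

test_that("empty candidate set returns the intercept-only model", {
  co <- generate_cohort(small_config(seed = 3))
  fit <- stepwise_select(co, "late", character(0))
  expect_equal(nrow(fit$coefficients), 1L)
  rs <- risk_score(fit, co)
  expect_equal(unique(round(rs$probability, 10)),
               round(mean(co$late), 10))
})

test_that("duplicated regressors contribute zero R-squared change", {
  co <- generate_cohort(small_config(seed = 12))
  co$lvo_copy <- co$lvo
  expect_warning(
    b <- hierarchical_blocks(co, "late", list(c("hyperlipemia", "lvo"),
                                              "lvo_copy")),
    "rank-deficient"
  )
  expect_equal(b$summary$delta_r_squared[2], 0, tolerance = 1e-12)
  expect_equal(b$summary$f_change[2], 0)
  expect_equal(b$summary$p_change[2], 1)
})

test_that("F-change equals the residual-sum-of-squares oracle on a toy design", {
  set.seed(4)
  n <- 40
  d <- tibble::tibble(
    a = rnorm(n), b = rnorm(n), c = rnorm(n),
    late = runif(n) + 0.3 * rnorm(n) > 0.5
  )
  res <- hierarchical_blocks(d, "late", list("a", "b", "c"))

  y <- as.numeric(d$late)
  sse <- function(preds) {
    X <- cbind(1, as.matrix(d[preds]))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  sst <- sum((y - mean(y))^2)
  r2_2 <- 1 - sse(c("a", "b")) / sst
  r2_3 <- 1 - sse(c("a", "b", "c")) / sst
  f3 <- ((r2_3 - r2_2) / 1) / ((1 - r2_3) / (n - 3 - 1))
  expect_equal(res$summary$delta_r_squared[3], r2_3 - r2_2, tolerance = 1e-12)
  expect_equal(res$summary$f_change[3], f3, tolerance = 1e-10)
  expect_equal(res$summary$p_change[3],
               pf(f3, 1, n - 4, lower.tail = FALSE), tolerance = 1e-12)

  # coefficients and overall F agree with lm/summary.lm
  ref <- summary(lm(y ~ a + b + c, data = d))
  expect_equal(res$coefficients[[3]]$estimate, unname(coef(ref)[, 1]),
               tolerance = 1e-10)
  expect_equal(res$coefficients[[3]]$std_error, unname(coef(ref)[, 2]),
               tolerance = 1e-10)
  expect_equal(res$summary$f_value[3], unname(ref$fstatistic[1]),
               tolerance = 1e-10)
  expect_equal(res$summary$adj_r_squared[3], ref$adj.r.squared,
               tolerance = 1e-12)
})

test_that("R-squared is non-decreasing across nested blocks on random designs", {
  set.seed(15)
  for (i in 1:10) {
    n <- 60
    d <- tibble::as_tibble(matrix(rnorm(n * 6), n, 6),
                           .name_repair = ~ paste0("v", 1:6))
    d$late <- runif(n) > 0.5
    b <- hierarchical_blocks(d, "late",
                             list(c("v1", "v2"), c("v3"), c("v4", "v5", "v6")))
    expect_true(all(diff(b$summary$r_squared) >= -1e-12))
    expect_true(all(b$summary$delta_r_squared >= -1e-12))
  }
})

test_that("the logistic block family reports deviance-based changes", {
  co <- generate_cohort(small_config(seed = 18))
  b <- hierarchical_blocks(co, "late", list("hyperlipemia", "lvo", "sir"),
                           family = "logistic")
  expect_true(all(diff(b$summary$r_squared) >= -1e-12))
  expect_true(all(b$summary$f_change >= -1e-8))
})

test_that("risk scores match a hand-computed logit and drop incomplete rows", {
  co <- generate_cohort(small_config(seed = 10))
  fit <- fit_logistic(co, "late", c("hyperlipemia", "lvo", "sir"))
  rs <- risk_score(fit, co)
  b <- fit$coefficients$estimate
  eta1 <- b[1] + b[2] * co$hyperlipemia[7] + b[3] * co$lvo[7] + b[4] * co$sir[7]
  expect_equal(rs$linear_predictor[7], eta1, tolerance = 1e-12)
  expect_equal(rs$probability[7], plogis(eta1), tolerance = 1e-12)

  co2 <- co
  co2$sir[3] <- NA
  expect_message(rs2 <- risk_score(fit, co2), "excluded")
  expect_equal(attr(rs2, "n_dropped"), 1L)
  expect_false(3 %in% rs2$.row)
})

test_that("Wald CIs cover generating coefficients at the nominal rate", {
  covered <- matrix(NA, 200, 2)
  for (s in 1:200) {
    set.seed(5000 + s)
    n <- 400
    x1 <- rnorm(n)
    x2 <- runif(n) > 0.5
    beta <- c(-0.3, 0.8, 0.6)
    p <- plogis(beta[1] + beta[2] * x1 + beta[3] * x2)
    d <- tibble::tibble(x1 = x1, x2 = x2, late = runif(n) < p)
    f <- fit_logistic(d, "late", c("x1", "x2"))
    lo <- f$coefficients$estimate - qnorm(0.975) * f$coefficients$std_error
    hi <- f$coefficients$estimate + qnorm(0.975) * f$coefficients$std_error
    covered[s, ] <- beta[2:3] >= lo[2:3] & beta[2:3] <= hi[2:3]
  }
  rates <- colMeans(covered)
  expect_true(all(rates >= 0.90 & rates <= 1.0))
})
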