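lvo_2x2 <- function() {
  counts <- table1_counts()
  e <- counts_to_vectors(111, counts$n_early, 177, counts$n_late)
  build_two_by_two(e$predictor, e$late)
}

hyperlip_2x2 <- function() {
  counts <- table1_counts()
  e <- counts_to_vectors(33, counts$n_early, 98, counts$n_late)
  build_two_by_two(e$predictor, e$late)
}

test_that("2x2 construction fixes the late-positive orientation", {
  t <- lvo_2x2()
  expect_equal(c(t$a, t$b, t$c, t$d), c(177, 98, 111, 247))
  t0 <- build_two_by_two(rep(FALSE, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(c(t0$a, t0$c), c(0, 0))
  expect_error(build_two_by_two(TRUE, c(TRUE, FALSE)),
               class = "flairsir_input_error")

  set.seed(42)
  p <- runif(20) > 0.5
  l <- runif(20) > 0.4
  t2 <- build_two_by_two(p, l)
  # exhaustive tally
  tally <- c(0, 0, 0, 0)
  for (i in 1:20) {
    tally <- tally + c(p[i] && l[i], !p[i] && l[i], p[i] && !l[i], !p[i] && !l[i])
  }
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), tally)
})

test_that("diagnostic metrics reproduce the reference hyperlipemia row", {
  m <- diagnostic_metrics(hyperlip_2x2())
  expect_equal(round(m$sensitivity, 3), 0.356)
  expect_equal(round(m$specificity, 3), 0.908)
  expect_equal(round(m$ppv, 3), 0.748)
  expect_equal(round(m$npv, 3), 0.647)
  expect_equal(round(m$accuracy, 3), 0.668)
  expect_equal(round(m$auc, 3), 0.632)
})

test_that("metrics handle perfect predictors and match direct formulas", {
  perfect <- structure(list(a = 10L, b = 0L, c = 0L, d = 12L),
                       class = "two_by_two")
  m <- diagnostic_metrics(perfect)
  expect_true(all(m[c("accuracy", "sensitivity", "specificity",
                      "ppv", "npv", "auc")] == 1))

  set.seed(3)
  for (i in 1:5) {
    cells <- rpois(4, 8) + 1
    t <- structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
                   class = "two_by_two")
    m <- diagnostic_metrics(t)
    expect_equal(m$sensitivity, cells[1] / (cells[1] + cells[2]))
    expect_equal(m$specificity, cells[4] / (cells[3] + cells[4]))
    expect_equal(m$ppv, cells[1] / (cells[1] + cells[3]))
    expect_equal(m$npv, cells[4] / (cells[2] + cells[4]))
    expect_equal(m$accuracy, (cells[1] + cells[4]) / sum(cells))
  }
})

test_that("odds ratios with Wald CIs reproduce the reference values", {
  or_h <- odds_ratio(hyperlip_2x2())
  expect_equal(or_h$or, 5.453, tolerance = 1e-3)
  expect_equal(or_h$ci_low, 3.530, tolerance = 1e-3)
  expect_equal(or_h$ci_high, 8.423, tolerance = 3e-4)
  expect_lt(or_h$p_value, 0.001)

  or_l <- odds_ratio(lvo_2x2())
  expect_equal(round(or_l$or, 3), 4.019)
  expect_equal(round(or_l$ci_low, 3), 2.880)
  expect_equal(round(or_l$ci_high, 3), 5.609)
})

test_that("a uniform table gives OR 1 with a CI symmetric about 1", {
  t <- structure(list(a = 7L, b = 7L, c = 7L, d = 7L), class = "two_by_two")
  o <- odds_ratio(t)
  expect_equal(o$or, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)
  expect_equal(o$p_value, 1)
})

test_that("Haldane correction matches the hand-computed corrected OR", {
  t <- structure(list(a = 12L, b = 0L, c = 5L, d = 9L), class = "two_by_two")
  expect_error(odds_ratio(t), class = "flairsir_input_error")
  o <- odds_ratio(t, correction = "haldane")
  expect_equal(o$or, (12.5 * 9.5) / (0.5 * 5.5), tolerance = 1e-12)
  se <- sqrt(1 / 12.5 + 1 / 0.5 + 1 / 5.5 + 1 / 9.5)
  expect_equal(o$ci_high, exp(log(o$or) + qnorm(0.975) * se), tolerance = 1e-12)
})

test_that("transposing predictor and outcome leaves the OR unchanged", {
  set.seed(9)
  p <- runif(40) > 0.5
  l <- runif(40) > 0.5
  o1 <- odds_ratio(build_two_by_two(p, l), correction = "haldane")
  o2 <- odds_ratio(build_two_by_two(l, p), correction = "haldane")
  expect_equal(o1$or, o2$or, tolerance = 1e-12)
})

test_that("binary mismatch scores reproduce the reference AUC 0.684", {
  counts <- table1_counts()
  e <- counts_to_vectors(205, counts$n_early, 56, counts$n_late)
  # absence of DWI-FLAIR mismatch scores 1 for a late window
  r <- roc_curve(as.numeric(!e$predictor), e$late)
  expect_equal(round(r$auc, 3), 0.684)
  # binary-predictor identity with the 2x2 metrics
  m <- diagnostic_metrics(build_two_by_two(!e$predictor, e$late))
  expect_equal(r$auc, m$auc, tolerance = 1e-12)
})

test_that("ROC handles separable and degenerate inputs", {
  r <- roc_curve(c(1, 2, 3, 11, 12, 13), rep(c(FALSE, TRUE), each = 3))
  expect_equal(r$auc, 1)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), class = "flairsir_input_error")
  expect_error(roc_curve(1:3, c(TRUE, FALSE)), class = "flairsir_input_error")
})

test_that("AUC equals the exhaustive concordant-pair fraction", {
  s <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  l <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
         TRUE, FALSE)
  expect_equal(roc_curve(s, l)$auc, auc_pairs(s, l), tolerance = 1e-12)
})

test_that("AUC identity with tie-corrected U holds on random inputs", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(6:25, 1)
    s <- sample(1:8, n, replace = TRUE) # heavy ties
    l <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    r <- roc_curve(s, l)
    expect_equal(r$auc, u_pairs(s[l], s[!l]) / (sum(l) * sum(!l)),
                 tolerance = 1e-12)
    # trapezoidal integral of the stepwise curve equals the U-based AUC
    expect_equal(sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2) +
                   (1 - r$fpr[length(r$fpr)]) * (1 + r$tpr[length(r$tpr)]) / 2,
                 r$auc, tolerance = 1e-12)
  }
})

test_that("negating scores maps AUC to its complement", {
  set.seed(5)
  s <- rnorm(40)
  l <- runif(40) > 0.45
  expect_equal(roc_curve(-s, l)$auc, 1 - roc_curve(s, l)$auc, tolerance = 1e-12)
})

test_that("DeLong variance agrees with pROC on a shared example", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- rnorm(60)
  l <- runif(60) > 0.5
  r <- roc_curve(s, l)
  pr <- pROC::roc(l, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$auc_variance, as.numeric(pROC::var(pr, method = "delong")),
               tolerance = 1e-10)
})

test_that("Youden cutoff conventions", {
  # binary predictor: conventional 0.5
  set.seed(2)
  p <- runif(30) > 0.5
  l <- p & (runif(30) > 0.2)
  l[1:3] <- TRUE
  r <- roc_curve(as.numeric(p), l)
  expect_equal(youden_cutoff(r)$threshold, 0.5)

  # separable scores: a mid-gap cutoff with J = 1
  r2 <- roc_curve(c(1, 2, 3, 11, 12, 13), rep(c(FALSE, TRUE), each = 3))
  y2 <- youden_cutoff(r2)
  expect_equal(y2$youden_j, 1)
  expect_gt(y2$threshold, 3)
  expect_lt(y2$threshold, 11)

  # random scores: matches exhaustive maximisation over all thresholds
  set.seed(14)
  s <- round(rnorm(30), 1)
  lab <- runif(30) > 0.5
  lab[1] <- TRUE; lab[2] <- FALSE
  y <- youden_cutoff(roc_curve(s, lab))
  grid <- sort(unique(c(s - 0.05, s + 0.05)))
  j_grid <- vapply(grid, function(th) {
    mean(s[lab] > th) + mean(s[!lab] <= th) - 1
  }, numeric(1))
  expect_equal(y$youden_j, max(j_grid), tolerance = 1e-12)
})

test_that("paired DeLong test matches the structural-component oracle", {
  # curve against itself: degenerate variance
  set.seed(7)
  s <- rnorm(20)
  l <- c(rep(TRUE, 10), rep(FALSE, 10))
  r <- roc_curve(s, l)
  self <- delong_paired_test(r, r)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)

  # n = 10 hand-rolled recomputation
  s1 <- c(0.3, 0.7, 0.2, 0.9, 0.5, 0.1, 0.8, 0.4, 0.6, 0.35)
  s2 <- c(0.5, 0.6, 0.1, 0.8, 0.7, 0.3, 0.4, 0.9, 0.2, 0.55)
  lab <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  d <- delong_paired_test(roc_curve(s1, lab), roc_curve(s2, lab))
  expect_equal(d$z, delong_z_oracle(s1, s2, lab), tolerance = 1e-12)

  # antisymmetry under swapping the curves
  d_rev <- delong_paired_test(roc_curve(s2, lab), roc_curve(s1, lab))
  expect_equal(d_rev$z, -d$z, tolerance = 1e-12)
  expect_error(
    delong_paired_test(roc_curve(s1, lab), roc_curve(s2, rev(lab))),
    class = "flairsir_input_error"
  )
})

test_that("paired DeLong agrees with pROC's roc.test", {
  skip_if_not_installed("pROC")
  set.seed(33)
  n <- 80
  l <- runif(n) > 0.5
  l[1] <- TRUE; l[2] <- FALSE
  base <- rnorm(n) + l
  s1 <- base + rnorm(n, 0, 0.8)
  s2 <- base + rnorm(n, 0, 1.2)
  ours <- delong_paired_test(roc_curve(s1, l), roc_curve(s2, l))
  theirs <- pROC::roc.test(pROC::roc(l, s1, quiet = TRUE, direction = "<"),
                           pROC::roc(l, s2, quiet = TRUE, direction = "<"),
                           method = "delong", paired = TRUE)
  expect_equal(abs(ours$z), abs(as.numeric(theirs$statistic)), tolerance = 1e-8)
  expect_equal(ours$p_value, as.numeric(theirs$p.value), tolerance = 1e-8)
})

test_that("Spearman correlation matches the closed form and cor.test", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)

  x <- c(2.3, 1.1, 5.6, 4.4, 3.2, 7.8, 6.1)
  y <- c(1.0, 0.4, 2.2, 3.1, 1.8, 2.9, 2.5)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman_cor(x, y)$rho, 1 - 6 * d2 / (7 * 48), tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(spearman_cor(x, y)$rho, unname(ct$estimate), tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), class = "flairsir_input_error")
  expect_error(spearman_cor(1:2, 2:1), class = "flairsir_input_error")
})

test_that("chi-squared and Mann-Whitney wrappers behave canonically", {
  t_eq <- build_two_by_two(rep(c(TRUE, FALSE), 20),
                           rep(c(TRUE, TRUE, FALSE, FALSE), 10))
  expect_equal(chi_square(t_eq)$statistic, 0, tolerance = 1e-12)

  expect_lt(chi_square(lvo_2x2())$p_value, 0.001)

  # against base R on the same table
  base <- suppressWarnings(
    stats::chisq.test(matrix(c(177, 98, 111, 247), 2), correct = FALSE)
  )
  expect_equal(chi_square(lvo_2x2())$statistic, unname(base$statistic),
               tolerance = 1e-10)

  x <- c(1.5, 2.5, 0.5); y <- c(2.0, 3.0, 4.0)
  expect_equal(mann_whitney(x, y)$statistic, u_pairs(x, y))
  expect_error(mann_whitney(numeric(0), y), class = "flairsir_input_error")

  empty_margin <- structure(list(a = 0L, b = 0L, c = 3L, d = 4L),
                            class = "two_by_two")
  expect_error(chi_square(empty_margin), class = "flairsir_input_error")
})

test_that("tidiers expose curve coordinates and summary statistics", {
  r <- roc_curve(c(1, 3, 2, 4), c(FALSE, TRUE, FALSE, TRUE))
  td <- tidy(r)
  expect_named(td, c("threshold", "tpr", "fpr"))
  expect_equal(glance(r)$auc, r$auc)
  expect_s3_class(autoplot(r), "ggplot")
})
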