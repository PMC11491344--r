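# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# AUC as the concordant-pair fraction over all late/early pairs, ties 1/2
auc_pairs <- function(scores, late) {
  x1 <- scores[late]
  x0 <- scores[!late]
  tot <- 0
  for (a in x1) for (b in x0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(x1) * length(x0))
}

# Mann-Whitney U of x against y by exhaustive pair counting
u_pairs <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# DeLong structural components from the definition (per-subject means of
# the Mann-Whitney kernel), plus variance/covariance of an AUC pair
delong_components <- function(scores, late) {
  x1 <- scores[late]
  x0 <- scores[!late]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x1, function(a) mean(vapply(x0, function(b) psi(a, b), 1)), 1)
  v01 <- vapply(x0, function(b) mean(vapply(x1, function(a) psi(a, b), 1)), 1)
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

delong_z_oracle <- function(s1, s2, late) {
  c1 <- delong_components(s1, late)
  c2 <- delong_components(s2, late)
  n1 <- sum(late); n0 <- sum(!late)
  v1 <- var(c1$v10) / n1 + var(c1$v01) / n0
  v2 <- var(c2$v10) / n1 + var(c2$v01) / n0
  cv <- cov(c1$v10, c2$v10) / n1 + cov(c1$v01, c2$v01) / n0
  (c1$auc - c2$auc) / sqrt(v1 + v2 - 2 * cv)
}

# expand a (early, late) count pair into subject-level logical vectors
counts_to_vectors <- function(pos_early, n_early, pos_late, n_late) {
  list(
    predictor = c(rep(TRUE, pos_early), rep(FALSE, n_early - pos_early),
                  rep(TRUE, pos_late), rep(FALSE, n_late - pos_late)),
    late = c(rep(FALSE, n_early), rep(TRUE, n_late))
  )
}

# small cohort config used where full study size is unnecessary
small_config <- function(seed = 1, ...) {
  cohort_config(n_early = 120L, n_late = 90L, seed = seed, ...)
}
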