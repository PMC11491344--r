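# internal numerical helpers

# log-normal parameters matched to a target median and interquartile range
lnorm_from_quartiles <- function(med, q1, q3) {
  stopifnot(q1 > 0, q1 < med, med < q3)
  list(meanlog = log(med), sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

# log-normal parameters such that the TRUNCATED distribution on
# (lower, upper] matches the target quartiles (least squares on the
# truncated CDF at the three targets)
lnorm_trunc_fit <- function(med, q1, q3, lower, upper) {
  start <- lnorm_from_quartiles(med, q1, q3)
  obj <- function(par) {
    ml <- par[1]; sl <- exp(par[2])
    plo <- stats::plnorm(lower, ml, sl)
    phi <- stats::plnorm(upper, ml, sl)
    if (phi - plo < 1e-6) return(1e6)
    pq <- (stats::plnorm(c(q1, med, q3), ml, sl) - plo) / (phi - plo)
    sum((pq - c(0.25, 0.5, 0.75))^2)
  }
  fit <- stats::optim(c(start$meanlog, log(start$sdlog)), obj,
                      method = "Nelder-Mead")
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

# inverse-CDF sampling from a log-normal truncated to (lower, upper]
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# round-half-up, the convention used when checking values against printed
# reference tables (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# draws from a multivariate normal via the Cholesky factor
rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  L <- chol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% L, 2, mu, `+`)
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}

# scoped RNG: run code under a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
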