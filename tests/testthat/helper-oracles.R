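# Independent oracles used to cross-check package computations.

# Breslow log-partial-likelihood for a binary covariate, maximised by a
# safeguarded Newton iteration. Written independently of the package's
# survival-based estimator so the two can be compared on fixtures.
oracle_cox_loghr <- function(time, status, arm, tol = 1e-10) {
  ev <- sort(unique(time[status == 1]))
  lpl_parts <- function(beta) {
    g <- 0; h <- 0; ll <- 0
    for (t in ev) {
      d <- status == 1 & time == t
      d1 <- sum(arm[d])
      at <- time >= t
      n0 <- sum(at & arm == 0); n1 <- sum(at & arm == 1)
      denom <- n0 + n1 * exp(beta)
      mu <- n1 * exp(beta) / denom
      ll <- ll + beta * d1 - sum(d) * log(denom)
      g <- g + d1 - sum(d) * mu
      h <- h - sum(d) * mu * (1 - mu)
    }
    list(ll = ll, g = g, h = h)
  }
  beta <- 0
  for (k in 1:50) {
    p <- lpl_parts(beta)
    step <- -p$g / p$h
    if (!is.finite(step)) break
    step <- max(min(step, 1), -1)
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# crude Monte-Carlo lower-orthant probability for a standard MVN
oracle_mvn_orthant <- function(u, R, n = 2e5) {
  L <- chol(R)
  z <- matrix(rnorm(n * length(u)), n) %*% L
  below <- sweep(z, 2, u, "<=")
  mean(rowSums(below) == length(u))
}

# deterministic small designs reused across tests
design_3stage <- function(...) {
  tams_design(alpha = c(0.5, 0.25, 0.025), omega = c(0.95, 0.95, 0.9),
              hr_alt = 0.75, accrual = 125, median_I = 1, median_D = 2, ...)
}

design_single <- function(accrual = 250, ...) {
  tams_design(alpha = 0.025, omega = 0.9, hr_alt = 0.75,
              accrual = accrual, median_D = 1, ...)
}
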