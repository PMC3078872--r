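#' Correlation between stagewise log hazard-ratio estimates
#'
#' For two looks on the same outcome, triggered at cumulative control-arm
#' event counts `e_i <= e_j`, the estimates of the log hazard ratio have
#' correlation `sqrt(e_i/e_j)` to an excellent approximation (exact for the
#' event-count-ratio estimator under the null when the two arms share the
#' event-time distribution).
#'
#' @param e_i,e_j cumulative control-arm event counts with `0 < e_i <= e_j`.
#' @return The correlation `sqrt(e_i/e_j)`.
#' @examples
#' stage_correlation(73, 140)   # 0.722
#' @export
stage_correlation <- function(e_i, e_j) {
  if (any(e_i <= 0)) stop("event counts must be positive")
  if (any(e_i > e_j)) stop("'e_i' must not exceed 'e_j' (pass the earlier stage first)")
  sqrt(e_i / e_j)
}

#' Cross-stage correlation matrix of log hazard-ratio estimates
#'
#' Builds the s x s correlation matrix `R` over the stagewise estimates:
#' within the intermediate stages (and between any stages sharing an outcome)
#' `R[i, j] = sqrt(e_i/e_j)`; between an intermediate stage and the final,
#' definitive-outcome stage the correlation is attenuated by the factor `c`,
#' `R[i, s] = c * sqrt(e_i/e_s)`. Setting `c = 1` (identical outcomes)
#' recovers the single-outcome form. Supplied `overrides` (e.g. empirically
#' estimated cross-outcome correlations) replace the analytic entries. If the
#' completed matrix has a negative eigenvalue below -1e-8 it is projected to
#' the nearest positive semi-definite correlation matrix (with a message).
#'
#' @param e vector of cumulative control-arm event counts, ascending within
#'   each outcome kind (intermediate counts for stages `1..s-1`, the
#'   definitive count for stage `s`).
#' @param attenuation cross-outcome attenuation factor `c` in (0, 1];
#'   `c = 1` treats all stages as sharing one outcome.
#' @param overrides optional matrix of the same dimension as `R`; non-`NA`
#'   entries replace the analytic values (symmetrised).
#' @param single_outcome if `TRUE`, no attenuation is applied to the final
#'   stage.
#' @return A correlation matrix with attributes `attenuation` and `source`.
#' @examples
#' correlation_matrix(c(73, 140, 264), attenuation = 0.6)
#' @export
correlation_matrix <- function(e, attenuation = 0.6, overrides = NULL,
                               single_outcome = FALSE) {
  s <- length(e)
  stopifnot(s >= 1, all(e > 0))
  if (s > 2 && any(diff(e[-s]) <= 0))
    stop("intermediate event counts must be strictly ascending")
  R <- diag(s)
  if (s > 1) {
    for (i in 1:(s - 1)) for (j in (i + 1):s) {
      rho <- stage_correlation(min(e[i], e[j]), max(e[i], e[j]))
      if (j == s && !single_outcome) rho <- attenuation * rho
      R[i, j] <- R[j, i] <- rho
    }
  }
  src <- "analytic"
  if (!is.null(overrides)) {
    stopifnot(is.matrix(overrides), all(dim(overrides) == s))
    idx <- which(!is.na(overrides), arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (i != j) R[i, j] <- R[j, i] <- overrides[i, j]
    }
    src <- "supplied"
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    message("correlation matrix not positive semi-definite (min eigenvalue ",
            signif(min(ev), 3), "); projecting to the nearest PSD matrix")
    R <- .nearest_psd(R)
  }
  attr(R, "attenuation") <- attenuation
  attr(R, "source") <- src
  R
}

# eigenvalue clipping followed by rescaling to unit diagonal
.nearest_psd <- function(R) {
  es <- eigen(R, symmetric = TRUE)
  vals <- pmax(es$values, 1e-10)
  R2 <- es$vectors %*% diag(vals, length(vals)) %*% t(es$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  (R2 + t(R2)) / 2
}

#' Lower orthant probability of a standard multivariate normal
#'
#' `P(Z_1 <= u_1, ..., Z_s <= u_s)` for a standard normal vector with
#' correlation matrix `R`. Uses Miwa's deterministic recursive integration
#' (so repeated calls give identical values); if `R` is numerically singular
#' a minimal ridge is applied first.
#'
#' @param u vector of thresholds.
#' @param R correlation matrix (positive semi-definite).
#' @return The orthant probability, absolute accuracy about 1e-6.
#' @export
mvn_orthant <- function(u, R) {
  s <- length(u)
  stopifnot(is.matrix(R), all(dim(R) == s))
  if (s == 1L) return(stats::pnorm(u))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  if (min(ev) < 1e-10) { # ridge away from exact singularity, renormalise
    R <- (R + diag(1e-8, s)) / (1 + 1e-8)
  }
  as.numeric(mvtnorm::pmvnorm(upper = u, corr = R,
                              algorithm = mvtnorm::Miwa(steps = 512)))
}

#' Overall and stagewise operating characteristics
#'
#' Computes the overall one-sided significance level `alpha` (probability
#' under the null of passing every stage) and overall power `omega`
#' (likewise under the alternative) from the multivariate normal model: the
#' stagewise standardised log hazard-ratio statistics are treated as jointly
#' normal with correlation matrix `R` from [correlation_matrix()], so
#' `alpha = P(Z_i <= qnorm(alpha_i) for all i; R)` and similarly for power
#' with the attained marginal powers. Also returned: the
#' intermediate-stages-only quantities (first `s - 1` stages), the
#' stagewise-conditional levels `alpha_{i|i-1}` and powers `omega_{i|i-1}`
#' (each joint probability divided by the previous one), and bounds over the
#' unknown cross-outcome correlation: by Slepian monotonicity the minimum is
#' at `c = 0` (independence between outcome types, where the joint
#' probability factorises as `alpha_I * alpha_s`) and the maximum at the
#' largest `c <= 1` keeping `R` positive semi-definite.
#'
#' The powers entering the integrals are the *attained* marginal powers of
#' the design (which exceed the nominal ones because event targets are
#' integers), not the nominal `omega_i`.
#'
#' @param design a `tams_design`, or a vector of cumulative control-arm event
#'   counts (in which case `alpha` and `power` must be given).
#' @param alpha,power stagewise significance levels and attained marginal
#'   powers; taken from `design` when it is a `tams_design`.
#' @param attenuation cross-outcome attenuation factor `c`; defaults to the
#'   design's value (0.6 if a bare event vector is given).
#' @param overrides optional correlation overrides, see
#'   [correlation_matrix()].
#' @param single_outcome all stages share one outcome; forced `TRUE` when the
#'   design declares identical hazards.
#' @return An object of class `tams_oc` with fields `alpha_overall`,
#'   `omega_overall`, `alpha_I`, `omega_I`, `alpha_conditional`,
#'   `omega_conditional`, `bounds` and the matrix `R`.
#' @examples
#' d <- tams_design(alpha = c(0.5, 0.25, 0.025), omega = c(0.95, 0.95, 0.9),
#'                  hr_alt = 0.75, accrual = 125, median_I = 1, median_D = 2)
#' tams_oc(d, attenuation = 0.6)
#' @export
tams_oc <- function(design, alpha = NULL, power = NULL, attenuation = NULL,
                    overrides = NULL, single_outcome = FALSE) {
  if (inherits(design, "tams_design")) {
    e <- design$stages$e_control
    if (is.null(alpha)) alpha <- design$spec$alpha
    if (is.null(power)) power <- design$stages$power_marginal
    if (is.null(attenuation)) attenuation <- design$spec$attenuation
    single_outcome <- single_outcome || design$spec$single_outcome
  } else {
    e <- design
    if (is.null(alpha) || is.null(power))
      stop("supply 'alpha' and 'power' when 'design' is an event vector")
    if (is.null(attenuation)) attenuation <- 0.6
  }
  s <- length(e)
  stopifnot(length(alpha) == s, length(power) == s)
  R <- correlation_matrix(e, attenuation, overrides, single_outcome)

  joint <- function(p, Rm) {
    vapply(seq_len(s), function(i) {
      mvn_orthant(stats::qnorm(p[seq_len(i)]), Rm[seq_len(i), seq_len(i),
                                                  drop = FALSE])
    }, numeric(1))
  }
  ja <- joint(alpha, R)
  jw <- joint(power, R)
  cond_a <- ja / c(1, ja[-s])
  cond_w <- jw / c(1, jw[-s])

  alpha_I <- if (s > 1) ja[s - 1] else 1
  omega_I <- if (s > 1) jw[s - 1] else 1

  if (single_outcome || s == 1) {
    bounds <- c(alpha_min = ja[s], alpha_max = ja[s],
                omega_min = jw[s], omega_max = jw[s])
    c_max_psd <- 1
  } else {
    # the orthant probability is increasing in every correlation (Slepian),
    # so the minimum sits at c = 0 -- where the final stage is independent of
    # the I-stages and the probability factorises exactly -- and the maximum
    # at the largest PSD-feasible attenuation
    a_min <- alpha_I * alpha[s]
    w_min <- omega_I * power[s]
    c_max_psd <- .largest_psd_c(e)
    Rmax <- correlation_matrix(e, c_max_psd, single_outcome = FALSE)
    a_max <- mvn_orthant(stats::qnorm(alpha), Rmax)
    w_max <- mvn_orthant(stats::qnorm(power), Rmax)
    bounds <- c(alpha_min = a_min, alpha_max = a_max,
                omega_min = w_min, omega_max = w_max)
  }

  structure(list(alpha_overall = ja[s], omega_overall = jw[s],
                 alpha_I = alpha_I, omega_I = omega_I,
                 alpha_conditional = cond_a, omega_conditional = cond_w,
                 alpha_marginal = alpha, omega_marginal = power,
                 bounds = bounds, attenuation = attenuation,
                 c_max_psd = c_max_psd, R = R, e = e),
            class = "tams_oc")
}

# largest attenuation factor (<= 1) keeping the analytic R PSD
.largest_psd_c <- function(e, tol = 1e-8) {
  ok <- function(cc) {
    R <- diag(length(e))
    s <- length(e)
    for (i in 1:(s - 1)) for (j in (i + 1):s) {
      rho <- sqrt(e[i] / e[j])
      if (j == s) rho <- cc * rho
      R[i, j] <- R[j, i] <- rho
    }
    min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= tol
  }
  if (ok(1)) return(1)
  lo <- 0; hi <- 1
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' @export
print.tams_oc <- function(x, digits = 4, ...) {
  s <- length(x$e)
  cat("Operating characteristics (multivariate normal model, c = ",
      format(x$attenuation), ")\n", sep = "")
  df <- data.frame(stage = seq_len(s),
                   alpha_marginal = round(x$alpha_marginal, digits),
                   alpha_conditional = round(x$alpha_conditional, digits),
                   omega_marginal = round(x$omega_marginal, digits),
                   omega_conditional = round(x$omega_conditional, digits))
  print(df, row.names = FALSE)
  cat("\nOverall: alpha =", round(x$alpha_overall, digits),
      " omega =", round(x$omega_overall, digits), "\n")
  if (s > 1)
    cat("Intermediate stages only: alpha_I =", round(x$alpha_I, digits),
        " omega_I =", round(x$omega_I, digits), "\n")
  b <- x$bounds
  cat("Bounds over c: alpha in [", round(b["alpha_min"], digits), ", ",
      round(b["alpha_max"], digits), "], omega in [",
      round(b["omega_min"], digits), ", ", round(b["omega_max"], digits),
      "]\n", sep = "")
  invisible(x)
}

#' Sensitivity of the overall operating characteristics to the attenuation
#'
#' Recomputes the overall significance level and power over a grid of
#' attenuation factors, using the analytic correlation structure only (no
#' overrides). The significance level roughly doubles over `c` in
#' `[0.4, 0.8]` while power moves little, so underestimating `c` is the
#' conservative direction.
#'
#' @inheritParams tams_oc
#' @param c_grid attenuation values in (0, 1].
#' @return A data frame with columns `c`, `alpha`, `omega`.
#' @export
tams_oc_sensitivity <- function(design, alpha = NULL, power = NULL,
                                c_grid = seq(0.4, 0.8, by = 0.1)) {
  stopifnot(all(c_grid > 0), all(c_grid <= 1))
  rows <- lapply(c_grid, function(cc) {
    oc <- tams_oc(design, alpha = alpha, power = power, attenuation = cc)
    data.frame(c = cc, alpha = oc$alpha_overall, omega = oc$omega_overall)
  })
  do.call(rbind, rows)
}

#' Attenuation factor from a fixed-time cross-outcome correlation
#'
#' Rule of thumb relating the attenuation factor `c` to the correlation
#' `rho_ID` between the log hazard-ratio estimates on the intermediate and
#' definitive outcomes at a fixed time-point: `c` is about 10 percent larger
#' than `rho_ID`, clamped at 1. A heuristic, flagged as such in reports.
#'
#' @param rho_ID fixed-time correlation, in (0, 0.9].
#' @return `min(1, 1.1 * rho_ID)`.
#' @export
c_from_rho <- function(rho_ID) {
  stopifnot(rho_ID > 0, rho_ID <= 0.9)
  pmin(1, 1.1 * rho_ID)
}
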