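#' Correlated exponential progression and death times
#'
#' Draws `n` pairs `(x, y)` with exact exponential marginals (hazards
#' `lambda_x`, `lambda_y`) and positive dependence, via a Gaussian copula:
#' `(U, V)` standard bivariate normal with correlation `rho`, then
#' `x = -log(pnorm(U))/lambda_x` and `y = -log(pnorm(V))/lambda_y`. Here `x`
#' plays the role of time to disease progression and `y` time to death; the
#' composite intermediate event time is `min(x, y)` (a patient may die before
#' progression is observed).
#'
#' @param n number of pairs.
#' @param lambda_x,lambda_y exponential hazards (> 0).
#' @param rho correlation of the underlying normals, |rho| < 1.
#' @return A two-column matrix with columns `x`, `y`.
#' @export
sample_bvexp <- function(n, lambda_x, lambda_y, rho) {
  stopifnot(n >= 1, lambda_x > 0, lambda_y > 0, abs(rho) < 1)
  u <- stats::rnorm(n)
  v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(x = -log(stats::pnorm(u)) / lambda_x,
        y = -log(stats::pnorm(v)) / lambda_y)
}

#' Hazard of the minimum of two correlated exponentials
#'
#' Monte-Carlo estimate of the hazard of `z = min(x, y)` under the Gaussian
#' copula construction, taken (as the distribution of `z` is close to
#' exponential) as the reciprocal of the sample mean of `z`. For `rho = 0`
#' the exact value is `lambda_x + lambda_y`; positive dependence lengthens
#' the minimum, so the hazard decreases with `rho`.
#'
#' @inheritParams sample_bvexp
#' @param n_cal Monte-Carlo sample size (1e5 or more recommended).
#' @return A list with the estimate `lambda` and its standard error `se`.
#' @export
hazard_of_min <- function(lambda_x, lambda_y, rho, n_cal = 1e5) {
  xy <- sample_bvexp(n_cal, lambda_x, lambda_y, rho)
  z <- pmin(xy[, 1], xy[, 2])
  m <- mean(z)
  list(lambda = 1 / m, se = stats::sd(z) / (sqrt(n_cal) * m^2))
}

#' Progression hazard matching a target composite hazard
#'
#' In practice the hazards of the observable outcomes are specified: the
#' death hazard `lambda_D` and the composite intermediate hazard `lambda_I`
#' of `z = min(x, y)`. This solves for the latent progression hazard
#' `lambda_x` such that the Monte-Carlo hazard of the minimum matches
#' `lambda_I`, using monotone bisection with common random numbers (the same
#' normal draws are reused at every candidate, making the objective smooth
#' and the solution reproducible).
#'
#' @param lambda_D death (definitive-outcome) hazard.
#' @param lambda_I target hazard of the composite intermediate outcome; must
#'   exceed `lambda_D`.
#' @param rho Gaussian-copula correlation in [0, 0.95].
#' @param n_cal Monte-Carlo sample size used in calibration.
#' @param rel_tol relative tolerance on the matched hazard (default 0.2%).
#' @return The solved `lambda_x`.
#' @export
solve_lambda_x <- function(lambda_D, lambda_I, rho, n_cal = 1e5,
                           rel_tol = 0.002) {
  stopifnot(lambda_D > 0, rho >= 0, rho <= 0.95)
  if (lambda_I <= lambda_D)
    stop("infeasible target: the composite hazard 'lambda_I' must exceed ",
         "the death hazard 'lambda_D' (the minimum fails at least as fast)")
  if (rho == 0) return(lambda_I - lambda_D)
  u <- stats::rnorm(n_cal)
  v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n_cal)
  eu <- -log(stats::pnorm(u))   # unit-exponential pair, correlated
  ev <- -log(stats::pnorm(v))
  hmin <- function(lx) 1 / mean(pmin(eu / lx, ev / lambda_D))
  lo <- lambda_I - lambda_D          # independence floor (rho >= 0)
  hi <- 2 * lambda_I
  while (hmin(hi) < lambda_I) hi <- hi * 2
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    h <- hmin(mid)
    if (abs(h - lambda_I) / lambda_I < rel_tol * 0.1) return(mid)
    if (h < lambda_I) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrated bivariate outcome model
#'
#' Builds the patient-level generator used by the trial simulator: death
#' times `y` are exponential with hazard `lambda_D`; composite intermediate
#' times are `z = min(x, y)` with the latent progression hazard solved by
#' [solve_lambda_x()] so that `z` has hazard `lambda_I`; and, because the
#' minimum of correlated exponentials is only approximately exponential, a
#' monotone quantile map (estimated from a large calibration sample) sends
#' the distribution of `z` to the exponential with hazard `lambda_I`,
#' yielding the corrected time `z'` that the simulator reports. The
#' correction is small and, except at very small `z`, shifts the
#' intermediate event slightly earlier.
#'
#' @param lambda_D death hazard (or give `median_D`).
#' @param lambda_I composite intermediate hazard (or `median_I`); must
#'   exceed `lambda_D`.
#' @param median_I,median_D medians, converted via `log(2)/median`.
#' @param rho Gaussian-copula correlation, default 0.6.
#' @param n_cal calibration sample size (default 1e6).
#' @param grid_size number of quantile knots stored for the correction map.
#' @return An object of class `outcome_model`.
#' @examples
#' set.seed(1)
#' m <- outcome_model(median_I = 1, median_D = 2, rho = 0.6, n_cal = 1e5)
#' head(sample_outcomes(m, 5))
#' @export
outcome_model <- function(lambda_D = NULL, lambda_I = NULL,
                          median_I = NULL, median_D = NULL, rho = 0.6,
                          n_cal = 1e6, grid_size = 16384) {
  if (is.null(lambda_D)) lambda_D <- log(2) / median_D
  if (is.null(lambda_I)) lambda_I <- log(2) / median_I
  stopifnot(rho >= 0, rho <= 0.95, n_cal >= 1e4)
  lambda_x <- solve_lambda_x(lambda_D, lambda_I, rho, n_cal = n_cal)
  # calibration sample of the composite time at the solved parameters
  xy <- sample_bvexp(n_cal, lambda_x, lambda_D, rho)
  z <- pmin(xy[, 1], xy[, 2])
  p <- (seq_len(grid_size) - 0.5) / grid_size
  structure(list(lambda_D = lambda_D, lambda_I = lambda_I,
                 lambda_x = lambda_x, rho = rho, n_cal = n_cal,
                 cal_p = p, cal_q = stats::quantile(z, probs = p,
                                                    names = FALSE, type = 8)),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat("Calibrated bivariate exponential outcome model\n")
  cat("  death hazard lambda_D:", format(x$lambda_D),
      "(median", format(round(log(2) / x$lambda_D, 3)), ")\n")
  cat("  composite intermediate hazard lambda_I:", format(x$lambda_I),
      "(median", format(round(log(2) / x$lambda_I, 3)), ")\n")
  cat("  latent progression hazard lambda_x:", format(round(x$lambda_x, 5)),
      " copula correlation rho:", format(x$rho), "\n")
  cat("  quantile correction calibrated on", x$n_cal, "draws\n")
  invisible(x)
}

#' Map composite times to the exponential scale
#'
#' Applies the model's monotone quantile correction: each `z` is carried to
#' its calibration-sample quantile and back through the exponential
#' (`lambda_I`) quantile function, so the corrected `z'` is exponential by
#' construction. Beyond the calibration range the map is extended by a
#' constant shift, preserving monotonicity. Patient ordering is preserved.
#'
#' @param z composite intermediate event times.
#' @param model an [outcome_model()].
#' @return Corrected times `z'`.
#' @export
exponentialize <- function(z, model) {
  stopifnot(inherits(model, "outcome_model"))
  q <- model$cal_q
  target <- stats::qexp(model$cal_p, rate = model$lambda_I)
  zc <- numeric(length(z))
  inside <- z >= q[1] & z <= q[length(q)]
  p <- stats::approx(q, model$cal_p, xout = z[inside], ties = "ordered")$y
  zc[inside] <- stats::qexp(p, rate = model$lambda_I)
  zc[z < q[1]] <- z[z < q[1]] * target[1] / q[1]
  hi <- z > q[length(q)]
  zc[hi] <- z[hi] + (target[length(q)] - q[length(q)])
  zc
}

#' Draw patient outcome pairs
#'
#' Samples `n` patients from a calibrated [outcome_model()]: corrected
#' composite intermediate times `z` (exponential with hazard `lambda_I`) and
#' death times `y` (exponential with hazard `lambda_D`), positively
#' dependent through the Gaussian copula.
#'
#' @param model an [outcome_model()].
#' @param n number of patients.
#' @return A data frame with columns `z` and `y`.
#' @export
sample_outcomes <- function(model, n) {
  xy <- sample_bvexp(n, model$lambda_x, model$lambda_D, model$rho)
  z <- exponentialize(pmin(xy[, 1], xy[, 2]), model)
  data.frame(z = z, y = xy[, 2])
}

#' Apply treatment hazard ratios to an outcome model
#'
#' Produces the experimental-arm generator under proportional hazards:
#' the intermediate-outcome hazard is multiplied by `hr_I` and the death
#' hazard by `hr_D`. Equal ratios rescale the calibrated model exactly
#' (time scales by `1/hr`); unequal ratios require re-solving the latent
#' progression hazard and recalibrating, which consumes random draws.
#'
#' @param model an [outcome_model()].
#' @param hr_I hazard ratio on the intermediate outcome, in (0, 1.5].
#' @param hr_D hazard ratio on the definitive outcome; defaults to `hr_I`.
#' @return A new `outcome_model`.
#' @export
apply_treatment <- function(model, hr_I, hr_D = hr_I) {
  stopifnot(inherits(model, "outcome_model"), hr_I > 0, hr_I <= 1.5,
            hr_D > 0, hr_D <= 1.5)
  if (hr_I == 1 && hr_D == 1) return(model)
  if (isTRUE(all.equal(hr_I, hr_D))) {
    m <- model
    m$lambda_D <- model$lambda_D * hr_D
    m$lambda_I <- model$lambda_I * hr_I
    m$lambda_x <- model$lambda_x * hr_I
    m$cal_q <- model$cal_q / hr_I
    return(m)
  }
  outcome_model(lambda_D = model$lambda_D * hr_D,
                lambda_I = model$lambda_I * hr_I,
                rho = model$rho, n_cal = model$n_cal,
                grid_size = length(model$cal_q))
}
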