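#' Log hazard ratio at an interim look
#'
#' Fits the proportional-hazards partial likelihood (Breslow tie handling)
#' comparing experimental with control on entry-to-event times, censoring
#' patients without an event at the look and excluding patients not yet
#' entered. If the experimental arm has no events the estimate is `-Inf`
#' (the look passes trivially); an event-free control arm gives `+Inf`.
#'
#' @param time follow-up times (entry to event or censoring).
#' @param status event indicator (1 = event, 0 = censored).
#' @param arm 0 = control, 1 = experimental.
#' @return A list with `loghr` and its standard error `se`.
#' @export
estimate_loghr <- function(time, status, arm) {
  stopifnot(length(time) == length(status), length(time) == length(arm))
  if (sum(status[arm == 1]) == 0) return(list(loghr = -Inf, se = Inf))
  if (sum(status[arm == 0]) == 0) return(list(loghr = Inf, se = Inf))
  ord <- order(time)
  y <- survival::Surv(time[ord], status[ord])
  fit <- survival::coxph.fit(x = matrix(as.numeric(arm[ord]), ncol = 1), y = y,
                             strata = NULL, offset = NULL, init = 0,
                             control = survival::coxph.control(),
                             weights = NULL, method = "breslow",
                             rownames = NULL)
  list(loghr = unname(fit$coefficients),
       se = sqrt(unname(fit$var[1, 1])))
}

# event-count-ratio estimate of the hazard ratio at a look:
# experimental events so far over allocation times control events
.count_ratio_hr <- function(o_exp, e_control, allocation) {
  o_exp / (allocation * e_control)
}

# patient entry times for one arm over the design's recruiting period
.arrivals <- function(rates, boundaries, t_stop, mode) {
  b0 <- c(0, boundaries[-length(boundaries)])
  out <- vector("list", length(rates))
  for (j in seq_along(rates)) {
    lo <- min(b0[j], t_stop); hi <- min(boundaries[j], t_stop)
    d <- hi - lo
    if (d <= 0) next
    n <- if (mode == "poisson") stats::rpois(1, rates[j] * d)
         else round(rates[j] * d)
    if (n > 0)
      out[[j]] <- if (mode == "poisson") lo + sort(stats::runif(n)) * d
                  else lo + (seq_len(n) - 0.5) * d / n
  }
  unlist(out, use.names = FALSE)
}

#' Simulate one multi-stage trial
#'
#' Generates patient-level data for a single replicate of a design and runs
#' the stagewise lack-of-benefit rule: looks 1 to s-1 are triggered when the
#' cumulative control-arm intermediate-event count reaches the design target
#' and analyse the intermediate outcome; look s is triggered by the
#' definitive-event target and analyses the definitive outcome. At each look
#' the trial continues if the estimated hazard ratio does not exceed the
#' stage's critical value.
#'
#' @param design a [tams_design()].
#' @param hr_I,hr_D true hazard ratios on the intermediate and definitive
#'   outcomes (1 under the null; `hr_D` defaults to `hr_I`).
#' @param model optional calibrated [outcome_model()] for the control arm
#'   (at the design's hazards). Required when the design uses distinct
#'   outcomes; the experimental-arm model is derived with
#'   [apply_treatment()]. Ignored for single-outcome designs.
#' @param model_exp optional pre-derived experimental-arm model (avoids
#'   repeated recalibration inside [tams_simulate()]).
#' @param arrivals `"uniform"` (deterministic stagewise-uniform entry,
#'   matching the design's expected-event calculus) or `"poisson"`.
#' @param estimator `"cox"` (partial likelihood) or `"counts"` (event-count
#'   ratio, the quantity whose cross-stage correlation is
#'   `sqrt(e_i/e_j)`).
#' @param stop_on_fail stop at the first failed look (default). Set `FALSE`
#'   to record estimates at every stage regardless, as needed for
#'   correlation studies.
#' @return A list with per-stage vectors `look_time`, `loghr`, `pass`, the
#'   `stop_stage` (s + 1 if all passed... see Details), and
#'   `info_fraction` (control definitive events at stopping over the
#'   definitive target).
#' @export
simulate_trial <- function(design, hr_I = 1, hr_D = hr_I, model = NULL,
                           model_exp = NULL,
                           arrivals = c("uniform", "poisson"),
                           estimator = c("cox", "counts"),
                           stop_on_fail = TRUE, cross_estimates = FALSE) {
  arrivals <- match.arg(arrivals)
  estimator <- match.arg(estimator)
  spec <- design$spec
  df <- design$stages
  s <- spec$n_stages
  t_stop <- if (is.null(spec$recruit_stop)) df$t_end[s] else spec$recruit_stop

  entry_c <- .arrivals(spec$accrual, df$t_end, t_stop, arrivals)
  entry_e <- .arrivals(spec$allocation * spec$accrual, df$t_end, t_stop,
                       arrivals)
  n_c <- length(entry_c); n_e <- length(entry_e)

  if (spec$single_outcome) {
    y_c <- stats::rexp(n_c, spec$hazard_D)
    y_e <- stats::rexp(n_e, spec$hazard_D * hr_D)
    z_c <- y_c; z_e <- y_e
  } else {
    if (is.null(model))
      stop("a calibrated 'outcome_model' is required for designs with ",
           "distinct intermediate and definitive outcomes")
    if (is.null(model_exp))
      model_exp <- apply_treatment(model, hr_I = hr_I, hr_D = hr_D)
    oc_ <- sample_outcomes(model, n_c)
    oe_ <- sample_outcomes(model_exp, n_e)
    z_c <- oc_$z; y_c <- oc_$y
    z_e <- oe_$z; y_e <- oe_$y
  }
  zcal_c <- entry_c + z_c; ycal_c <- entry_c + y_c
  zcal_e <- entry_e + z_e; ycal_e <- entry_e + y_e
  zcal_c_sorted <- sort(zcal_c)
  ycal_c_sorted <- sort(ycal_c)

  look_time <- loghr <- numeric(s)
  loghr_D_at_look <- rep(NA_real_, s)
  pass <- logical(s)
  stop_stage <- s + 1L
  for (i in seq_len(s)) {
    final <- (i == s)
    e_target <- df$e_control[i]
    trig_sorted <- if (final) ycal_c_sorted else zcal_c_sorted
    if (length(trig_sorted) < e_target) {
      # cannot ever observe the target (too few control patients recruited)
      look_time[i] <- Inf; loghr[i] <- NA_real_; pass[i] <- NA
      if (stop_stage > s) stop_stage <- i
      break
    }
    lt <- trig_sorted[e_target]
    look_time[i] <- lt
    if (estimator == "counts") {
      ocal <- if (final) ycal_e else zcal_e
      hr_hat <- .count_ratio_hr(sum(ocal <= lt), e_target, spec$allocation)
      loghr[i] <- log(hr_hat)
    } else {
      ecal_c <- if (final) ycal_c else zcal_c
      ecal_e <- if (final) ycal_e else zcal_e
      t_c <- if (final) y_c else z_c
      t_e <- if (final) y_e else z_e
      in_c <- entry_c < lt; in_e <- entry_e < lt
      time <- c(pmin(t_c[in_c], lt - entry_c[in_c]),
                pmin(t_e[in_e], lt - entry_e[in_e]))
      status <- c(as.integer(ecal_c[in_c] <= lt),
                  as.integer(ecal_e[in_e] <= lt))
      arm <- c(rep(0L, sum(in_c)), rep(1L, sum(in_e)))
      loghr[i] <- estimate_loghr(time, status, arm)$loghr
    }
    if (cross_estimates && !final) {
      # definitive-outcome estimate at the same calendar time
      in_c <- entry_c < lt; in_e <- entry_e < lt
      timeD <- c(pmin(y_c[in_c], lt - entry_c[in_c]),
                 pmin(y_e[in_e], lt - entry_e[in_e]))
      statusD <- c(as.integer(ycal_c[in_c] <= lt),
                   as.integer(ycal_e[in_e] <= lt))
      armD <- c(rep(0L, sum(in_c)), rep(1L, sum(in_e)))
      loghr_D_at_look[i] <- estimate_loghr(timeD, statusD, armD)$loghr
    }
    pass[i] <- loghr[i] <= log(df$delta[i])
    if (!pass[i] && stop_on_fail) { stop_stage <- i; break }
    if (!pass[i] && stop_stage > s) stop_stage <- i
  }
  stop_time <- if (stop_stage > s) look_time[s] else look_time[stop_stage]
  info <- if (stop_stage > s) 1.0 else
    sum(ycal_c_sorted <= stop_time) / df$e_control[s]
  list(look_time = look_time, loghr = loghr,
       loghr_D_at_look = loghr_D_at_look, pass = pass,
       stop_stage = stop_stage, info_fraction = info,
       n_control = n_c, n_total = n_c + n_e)
}

#' Monte-Carlo operating characteristics of a design
#'
#' Replicates [simulate_trial()] and summarises the empirical stagewise
#' conditional pass probabilities (significance levels under the null,
#' powers under the alternative), the overall pass probability, and the mean
#' information fraction at stopping. Conditional probabilities at stage i
#' are computed among replicates that passed stage i-1; Monte-Carlo standard
#' errors use the binomial formula with the conditioning replicate count.
#'
#' @inheritParams simulate_trial
#' @param nsim number of replicate trials (>= 100 recommended).
#' @param seed optional integer seed; replicate seeds are derived from it so
#'   results are reproducible and independent of `nsim` chunking.
#' @param rho Gaussian-copula correlation used to build the outcome model
#'   when `model` is not supplied (distinct-outcome designs only).
#' @param n_cal calibration sample size for the internally built model.
#' @return An object of class `tams_sim`: empirical conditional and overall
#'   pass probabilities with standard errors, the per-stage log hazard-ratio
#'   estimates, and the mean information fraction at stopping.
#' @examples
#' \donttest{
#' d <- tams_design(alpha = c(0.25, 0.025), omega = c(0.95, 0.9),
#'                  hr_alt = 0.75, accrual = 250, median_I = 1, median_D = 1)
#' tams_simulate(d, nsim = 200, hr_I = 1, seed = 7)
#' }
#' @export
tams_simulate <- function(design, nsim = 1000, hr_I = 1, hr_D = hr_I,
                          model = NULL, arrivals = c("uniform", "poisson"),
                          estimator = c("cox", "counts"), seed = NULL,
                          rho = 0.6, n_cal = 2e5, stop_on_fail = TRUE) {
  arrivals <- match.arg(arrivals)
  estimator <- match.arg(estimator)
  stopifnot(nsim >= 1)
  if (!is.null(seed)) set.seed(seed)
  spec <- design$spec
  if (!spec$single_outcome && is.null(model))
    model <- outcome_model(lambda_D = spec$hazard_D, lambda_I = spec$hazard_I,
                           rho = rho, n_cal = n_cal)
  model_exp <- if (!spec$single_outcome)
    apply_treatment(model, hr_I = hr_I, hr_D = hr_D) else NULL
  s <- spec$n_stages
  rep_seeds <- sample.int(.Machine$integer.max - 1L, nsim)

  pass <- matrix(NA, nsim, s)
  loghr <- matrix(NA_real_, nsim, s)
  info <- numeric(nsim)
  flagged <- 0L
  for (r in seq_len(nsim)) {
    set.seed(rep_seeds[r])
    tr <- simulate_trial(design, hr_I = hr_I, hr_D = hr_D, model = model,
                         model_exp = model_exp, arrivals = arrivals,
                         estimator = estimator, stop_on_fail = stop_on_fail)
    pass[r, ] <- tr$pass
    loghr[r, ] <- tr$loghr
    info[r] <- tr$info_fraction
    if (anyNA(tr$pass[seq_len(min(tr$stop_stage, s))])) flagged <- flagged + 1L
  }
  reached <- matrix(FALSE, nsim, s)
  reached[, 1] <- TRUE
  if (s > 1) for (i in 2:s)
    reached[, i] <- reached[, i - 1] & !is.na(pass[, i - 1]) & pass[, i - 1]
  n_reached <- colSums(reached)
  p_cond <- vapply(seq_len(s), function(i)
    mean(pass[reached[, i], i], na.rm = TRUE), numeric(1))
  se_cond <- sqrt(p_cond * (1 - p_cond) / pmax(n_reached, 1))
  all_pass <- reached[, s] & !is.na(pass[, s]) & pass[, s]
  p_overall <- mean(all_pass)
  structure(list(nsim = nsim, estimator = estimator, arrivals = arrivals,
                 hr_I = hr_I, hr_D = hr_D,
                 pass_conditional = p_cond, se_conditional = se_cond,
                 n_reached = n_reached,
                 overall = p_overall,
                 se_overall = sqrt(p_overall * (1 - p_overall) / nsim),
                 info_fraction = mean(info),
                 loghr = loghr, pass = pass, flagged = flagged,
                 e_control = design$stages$e_control, seed = seed),
            class = "tams_sim")
}

#' @export
print.tams_sim <- function(x, digits = 4, ...) {
  cat("Simulated operating characteristics (", x$nsim, " replicates, ",
      x$estimator, " estimator, ", x$arrivals, " arrivals)\n", sep = "")
  cat("  true HR (I, D): ", x$hr_I, ", ", x$hr_D, "\n", sep = "")
  df <- data.frame(stage = seq_along(x$pass_conditional),
                   pass_conditional = round(x$pass_conditional, digits),
                   se = round(x$se_conditional, digits),
                   n_reached = x$n_reached)
  print(df, row.names = FALSE)
  cat("Overall pass probability:", round(x$overall, digits),
      "(se", round(x$se_overall, digits), ")\n")
  cat("Mean information fraction at stopping:",
      round(x$info_fraction, 3), "\n")
  if (x$flagged > 0)
    cat("Replicates with unreachable event targets:", x$flagged, "\n")
  invisible(x)
}

#' @rdname tams_simulate
#' @param object a `tams_design` (generic-conforming argument name).
#' @param ... passed to [tams_simulate()].
#' @export
simulate.tams_design <- function(object, nsim = 1000, seed = NULL, ...) {
  tams_simulate(object, nsim = nsim, seed = seed, ...)
}

#' Empirical cross-stage correlations and attenuation factor
#'
#' Runs the design without early stopping, recording the stagewise hazard
#' ratio estimates in every replicate, and returns their empirical Pearson
#' correlation matrix. For designs with distinct outcomes the per-stage
#' attenuation estimates `c_i = R[i, s] / sqrt(e_i/e_s)` are returned; when
#' `fixed_time_rho = TRUE`, the correlation between the intermediate- and
#' definitive-outcome log hazard ratios evaluated at the same calendar time
#' (each intermediate look) is also estimated.
#'
#' @inheritParams tams_simulate
#' @param fixed_time_rho also estimate the fixed-time cross-outcome
#'   correlation (needs the Cox estimator; slower).
#' @param use_log correlate log estimates (default) rather than ratios.
#' @return A list with `R` (empirical correlations), `c_hat` (per-stage
#'   attenuation estimates, `NA` for single-outcome designs), and optionally
#'   `rho_ID` per intermediate stage.
#' @export
estimate_cross_correlation <- function(design, nsim = 1000, hr_I = 1,
                                       hr_D = hr_I, model = NULL,
                                       arrivals = c("poisson", "uniform"),
                                       estimator = c("counts", "cox"),
                                       seed = NULL, rho = 0.6, n_cal = 2e5,
                                       fixed_time_rho = FALSE,
                                       use_log = TRUE) {
  arrivals <- match.arg(arrivals)
  estimator <- match.arg(estimator)
  if (!is.null(seed)) set.seed(seed)
  spec <- design$spec
  s <- spec$n_stages
  if (!spec$single_outcome && is.null(model))
    model <- outcome_model(lambda_D = spec$hazard_D, lambda_I = spec$hazard_I,
                           rho = rho, n_cal = n_cal)
  model_exp <- if (!spec$single_outcome)
    apply_treatment(model, hr_I = hr_I, hr_D = hr_D) else NULL
  rep_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  est <- matrix(NA_real_, nsim, s)
  estD <- if (fixed_time_rho && s > 1) matrix(NA_real_, nsim, s - 1) else NULL
  for (r in seq_len(nsim)) {
    set.seed(rep_seeds[r])
    tr <- simulate_trial(design, hr_I = hr_I, hr_D = hr_D, model = model,
                         model_exp = model_exp, arrivals = arrivals,
                         estimator = estimator, stop_on_fail = FALSE,
                         cross_estimates = fixed_time_rho)
    est[r, ] <- if (use_log) tr$loghr else exp(tr$loghr)
    if (!is.null(estD)) estD[r, ] <- tr$loghr_D_at_look[seq_len(s - 1)]
  }
  ok <- stats::complete.cases(est) & apply(is.finite(est), 1, all)
  R <- stats::cor(est[ok, , drop = FALSE])
  c_hat <- if (spec$single_outcome) rep(NA_real_, max(s - 1, 0)) else
    R[seq_len(s - 1), s] / sqrt(design$stages$e_control[seq_len(s - 1)] /
                                  design$stages$e_control[s])
  rho_ID <- NULL
  if (!is.null(estD)) {
    rho_ID <- vapply(seq_len(s - 1), function(i) {
      okD <- ok & is.finite(estD[, i])
      stats::cor(est[okD, i], estD[okD, i])
    }, numeric(1))
  }
  list(R = R, c_hat = c_hat, rho_ID = rho_ID, n_used = sum(ok),
       estimator = estimator)
}

#' Bias diagnostics for the single-stage normal approximations
#'
#' For a grid of single-stage designs, simulates the standardised log
#' hazard-ratio statistics whose distribution should be standard normal if
#' the design's variance approximations were exact: under the null,
#' `A1 = qnorm(alpha) + loghr/sigma0`; under the alternative,
#' `B1 = qnorm(omega) + (loghr - log(hr_alt))/sigma1`, with `sigma0`,
#' `sigma1` the design values. Departures of the standard deviations from 1
#' measure the bias of the respective variance approximation under
#' event-driven analysis; in practice they stay within a few percent of 1.
#'
#' @param alpha_grid,omega_grid vectors of stage significance levels and
#'   powers; the grid is their cross product.
#' @param nsim replicates per cell and hypothesis.
#' @param accrual control-arm accrual rate.
#' @param hazard event hazard (single outcome).
#' @param hr_alt alternative hazard ratio.
#' @param seed optional integer seed.
#' @return A data frame with one row per (alpha, omega) cell: means and SDs
#'   of `A1` (null) and `B1` (alternative) and their reference values.
#' @export
diagnostics_bias <- function(alpha_grid = c(0.5, 0.25, 0.1, 0.05, 0.025),
                             omega_grid = c(0.9, 0.95, 0.99),
                             nsim = 2000, accrual = 250, hazard = 0.693,
                             hr_alt = 0.75, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (a in alpha_grid) for (w in omega_grid) {
    d <- tams_design(alpha = a, omega = w, hr_alt = hr_alt,
                     accrual = accrual, hazard_D = hazard)
    e <- d$stages$e_control
    sigma0 <- sqrt(variance_null(e, d$spec$allocation))
    sigma1 <- sqrt(variance_alt(e, d$stages$e_exp_alt))
    sim0 <- tams_simulate(d, nsim = nsim, hr_I = 1)
    sim1 <- tams_simulate(d, nsim = nsim, hr_I = hr_alt)
    A1 <- stats::qnorm(a) + sim0$loghr[, 1] / sigma0
    B1 <- stats::qnorm(w) + (sim1$loghr[, 1] - log(hr_alt)) / sigma1
    rows[[length(rows) + 1L]] <- data.frame(
      alpha = a, omega = w, z_alpha = stats::qnorm(a), z_omega = stats::qnorm(w),
      mean_A1 = mean(A1, na.rm = TRUE), sd_A1 = stats::sd(A1, na.rm = TRUE),
      mean_B1 = mean(B1, na.rm = TRUE), sd_B1 = stats::sd(B1, na.rm = TRUE))
  }
  do.call(rbind, rows)
}
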