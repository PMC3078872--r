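#' Variance of the log hazard ratio under the null
#'
#' Large-sample approximation `(1 + 1/A)/e`, where `e` is the cumulative
#' control-arm event count and `A` the allocation ratio. Under the null the
#' experimental arm accumulates events at `A` times the control rate, so the
#' information is `e / (1 + 1/A)`.
#'
#' @param e control-arm event count (>= 1).
#' @param allocation allocation ratio A > 0.
#' @return Approximate variance of the estimated log hazard ratio.
#' @examples
#' sqrt(variance_null(264, 1))  # sigma0 used for the final-stage boundary
#' @export
variance_null <- function(e, allocation) {
  if (any(e <= 0) || allocation <= 0) stop("'e' and 'allocation' must be positive")
  (1 + 1 / allocation) / e
}

#' Variance of the log hazard ratio under the alternative
#'
#' Sum of reciprocal event counts in the two arms, `1/e_control + 1/e_exp`.
#' Under the alternative the experimental arm sees fewer events, which this
#' form (unlike the null approximation) accounts for.
#'
#' @param e_control control-arm events (>= 1).
#' @param e_exp experimental-arm events expected under the alternative (> 0;
#'   need not be an integer).
#' @return Approximate variance of the estimated log hazard ratio.
#' @export
variance_alt <- function(e_control, e_exp) {
  if (any(e_control <= 0) || any(e_exp <= 0)) stop("event counts must be positive")
  1 / e_control + 1 / e_exp
}

#' Critical hazard ratio for a lack-of-benefit look
#'
#' The boundary `delta` solves `P(estimated log HR <= log delta | H0) = alpha`
#' for a normally distributed log hazard-ratio estimate:
#' `log delta = log hr_null + qnorm(alpha) * sigma0`. Recruitment stops for
#' lack of benefit when the estimated hazard ratio exceeds `delta`.
#'
#' @param alpha one-sided stage significance level in (0, 1).
#' @param sigma0 standard deviation of the log HR estimate under the null.
#' @param hr_null null hazard ratio (usually 1).
#' @return Critical hazard ratio `delta`; equals `hr_null` when `alpha = 0.5`.
#' @examples
#' critical_hr(0.025, sqrt(variance_null(262, 1)))  # 0.843
#' @export
critical_hr <- function(alpha, sigma0, hr_null = 1) {
  stopifnot(alpha > 0, alpha < 1, sigma0 > 0, hr_null > 0)
  exp(log(hr_null) + stats::qnorm(alpha) * sigma0)
}

#' Marginal power attained at a stage
#'
#' Probability under the alternative that the estimated hazard ratio falls
#' below the critical value: `pnorm((log delta - log hr_alt)/sigma1)`.
#'
#' @param delta critical hazard ratio for the stage.
#' @param hr_alt alternative hazard ratio (< null).
#' @param sigma1 standard deviation of the log HR estimate under the
#'   alternative.
#' @return Marginal probability of passing the stage under the alternative.
#' @export
attained_power <- function(delta, hr_alt, sigma1) {
  stopifnot(sigma1 > 0)
  stats::pnorm((log(delta) - log(hr_alt)) / sigma1)
}

#' Starting value for the stagewise event iteration
#'
#' Closed-form event count from the null-variance approximation:
#' `ceiling((1 + 1/A) * (qnorm(omega) - qnorm(alpha))^2 / log(hr_null/hr_alt)^2)`,
#' floored at 1. This undershoots the final target because the alternative
#' variance exceeds the null approximation; the iteration in [tams_design()]
#' then climbs to the smallest count meeting the power requirement.
#'
#' @inheritParams critical_hr
#' @param omega stage power in (0, 1).
#' @param hr_alt alternative hazard ratio, `0 < hr_alt < hr_null`.
#' @param allocation allocation ratio A > 0.
#' @return Integer starting event count.
#' @export
initial_events <- function(alpha, omega, hr_null = 1, hr_alt, allocation = 1) {
  if (hr_alt >= hr_null) stop("'hr_alt' must be smaller than 'hr_null'")
  stopifnot(alpha > 0, alpha < 1, omega > 0, omega < 1, allocation > 0)
  e0 <- (1 + 1 / allocation) * (stats::qnorm(omega) - stats::qnorm(alpha))^2 /
    log(hr_null / hr_alt)^2
  max(1L, as.integer(ceiling(e0)))
}

# Solve one stage of the design: smallest integer control-arm event target
# whose attained power reaches the nominal power (within power_tol), together
# with the boundary, stage end-time and expected experimental events under H1.
solve_stage <- function(spec, i, prev) {
  s <- spec$n_stages
  final <- (i == s)
  hazard <- if (final) spec$hazard_D else spec$hazard_I
  # control-arm schedule: boundaries of the solved stages, current rate extended
  n_prev <- length(prev$t_end)
  sched <- accrual_schedule(
    rates = spec$accrual[seq_len(max(n_prev, 1L))],
    boundaries = if (n_prev) prev$t_end else Inf,
    recruit_stop = if (final) spec$recruit_stop else NULL
  )
  if (n_prev) {
    # stage i recruits at rate accrual[i] after the last solved boundary
    sched$rates <- c(spec$accrual[seq_len(n_prev)], spec$accrual[i])
    sched$boundaries <- c(prev$t_end, prev$t_end[n_prev] + 1)
  } else {
    sched <- accrual_schedule(spec$accrual[i], 1e9,
                              recruit_stop = if (final) spec$recruit_stop else NULL)
  }
  # experimental arm: same stage structure, rates scaled by A, hazard scaled
  # by the stagewise alternative hazard ratio
  exp_sched <- sched
  exp_sched$rates <- spec$allocation * sched$rates

  same_kind <- !final || spec$single_outcome
  e_floor <- if (n_prev && same_kind) prev$e_control[n_prev] + 1L else 1L
  e <- max(initial_events(spec$alpha[i], spec$omega[i], spec$hr_null[i],
                          spec$hr_alt[i], spec$allocation),
           e_floor)
  clamped <- e_floor > 1L && e == e_floor &&
    initial_events(spec$alpha[i], spec$omega[i], spec$hr_null[i],
                   spec$hr_alt[i], spec$allocation) < e_floor
  t_prev_kind <- if (n_prev && same_kind) prev$t_end[n_prev] else 0
  for (iter in seq_len(1e6)) {
    sigma0 <- sqrt(variance_null(e, spec$allocation))
    delta <- critical_hr(spec$alpha[i], sigma0, spec$hr_null[i])
    t_i <- time_for_events(e, sched, hazard, t_floor = t_prev_kind)
    e_exp <- events_at(t_i, exp_sched, spec$hr_alt[i] * hazard)
    pow <- attained_power(delta, spec$hr_alt[i], sqrt(variance_alt(e, e_exp)))
    if (pow >= spec$omega[i] - spec$power_tol) break
    e <- e + 1L
    if (iter == 1e6) stop("stage ", i, ": event iteration did not converge")
  }
  list(index = i, outcome_kind = if (final) "D" else "I", delta = delta,
       e_control = e, e_exp_alt = e_exp, t_end = t_i,
       power_marginal = pow, degenerate_clamp = clamped)
}

#' Construct a multi-stage lack-of-benefit trial design
#'
#' Computes, for each of `s` stages, the cumulative control-arm event target,
#' the critical hazard ratio below which the trial continues, the calendar
#' end-time of the stage and the attained marginal power. Stages `1..s-1`
#' screen the treatment on the intermediate outcome (hazard `hazard_I`); stage
#' `s` is the definitive analysis (hazard `hazard_D`). At each stage the event
#' target starts at the closed-form estimate from [initial_events()] and is
#' incremented by one event at a time until the attained power -- computed
#' from the alternative-hypothesis variance with the expected experimental-arm
#' events at the stage end-time -- reaches the nominal power. The returned
#' targets are therefore minimal: removing a single event drops the attained
#' power below nominal.
#'
#' Interim analyses are triggered by cumulative control-arm event counts, so
#' stage timings are identical under the null and the alternative (the control
#' arm is unaffected by treatment). Timings assume exponential event times and
#' stagewise-uniform accrual; violating the exponential assumption perturbs
#' only the timelines, not the event targets.
#'
#' @param alpha vector of one-sided stage significance levels, strictly
#'   descending (otherwise later stages are redundant).
#' @param omega vector of stage powers, same length.
#' @param hr_alt alternative hazard ratio(s); scalar or one per stage.
#'   Values on intermediate stages default to the definitive-stage value
#'   (conservative); a larger intermediate effect may be supplied per stage.
#' @param hr_null null hazard ratio(s), default 1.
#' @param allocation allocation ratio A: experimental patients per control
#'   patient. Default 1.
#' @param accrual control-arm accrual rate(s), patients per time-unit; scalar
#'   or one per stage. If `accrual_scope = "total"` the rates are interpreted
#'   as whole-trial rates and divided by `1 + allocation`.
#' @param accrual_scope `"control"` (default) or `"total"`.
#' @param hazard_I,hazard_D control-arm exponential hazards of the
#'   intermediate and definitive outcomes; alternatively give `median_I`,
#'   `median_D` (converted via `log(2)/median`).
#' @param median_I,median_D median event times, used when hazards are absent.
#' @param recruit_stop optional calendar time at which recruitment stops; must
#'   fall inside the final stage.
#' @param attenuation cross-outcome correlation attenuation factor `c` in
#'   (0, 1], used by [tams_oc()]. Default 0.6.
#' @param power_tol numerical slack accepted on the nominal stage power when
#'   terminating the event iteration. The default 2e-4 reproduces the stage
#'   targets printed by the reference software for this class of designs;
#'   set 0 for the strict rule.
#' @return An object of class `tams_design`: a list with `stages` (a data
#'   frame of per-stage quantities), `spec` (the validated parameter set),
#'   `total_patients` and a `degenerate` flag with message.
#' @examples
#' d <- tams_design(alpha = c(0.5, 0.25, 0.025), omega = c(0.95, 0.95, 0.9),
#'                  hr_alt = 0.75, accrual = 125,
#'                  median_I = 1, median_D = 2)
#' d
#' summary(d)
#' @seealso [tams_oc()] for operating characteristics, [simulate.tams_design()]
#'   for Monte-Carlo validation.
#' @export
tams_design <- function(alpha, omega, hr_alt, hr_null = 1, allocation = 1,
                        accrual, accrual_scope = c("control", "total"),
                        hazard_I = NULL, hazard_D = NULL,
                        median_I = NULL, median_D = NULL,
                        recruit_stop = NULL, attenuation = 0.6,
                        power_tol = 2e-4) {
  accrual_scope <- match.arg(accrual_scope)
  spec <- tams_spec(alpha = alpha, omega = omega, hr_alt = hr_alt,
                    hr_null = hr_null, allocation = allocation,
                    accrual = accrual, accrual_scope = accrual_scope,
                    hazard_I = hazard_I, hazard_D = hazard_D,
                    median_I = median_I, median_D = median_D,
                    recruit_stop = recruit_stop, attenuation = attenuation,
                    power_tol = power_tol)
  s <- spec$n_stages
  prev <- list(e_control = integer(0), t_end = numeric(0))
  stages <- vector("list", s)
  degenerate <- FALSE
  messages <- character(0)
  for (i in seq_len(s)) {
    if (i == s && !is.null(spec$recruit_stop) && s > 1 &&
        spec$recruit_stop <= prev$t_end[s - 1]) {
      stop("'recruit_stop' must fall strictly inside the final stage ",
           "(after t = ", round(prev$t_end[s - 1], 3), "): stopping ",
           "recruitment during an intermediate stage would make later ",
           "stages redundant")
    }
    st <- solve_stage(spec, i, prev)
    if (st$degenerate_clamp) {
      degenerate <- TRUE
      messages <- c(messages, paste0("stage ", i,
        ": event target forced above the previous stage; stage has (near) zero length"))
    }
    if (i > 1 && st$t_end <= prev$t_end[i - 1]) {
      degenerate <- TRUE
      messages <- c(messages, paste0("stage ", i, " ends no later than stage ",
                                     i - 1, " (non-positive duration)"))
    }
    prev$e_control <- c(prev$e_control, st$e_control)
    prev$t_end <- c(prev$t_end, st$t_end)
    stages[[i]] <- st
  }
  t_end <- vapply(stages, `[[`, numeric(1), "t_end")
  durations <- diff(c(0, t_end))
  if (!is.null(spec$recruit_stop) &&
      (s > 1 && spec$recruit_stop <= t_end[s - 1] || spec$recruit_stop >= t_end[s])) {
    stop("'recruit_stop' must fall strictly inside the final stage (",
         if (s > 1) round(t_end[s - 1], 3) else 0, ", ", round(t_end[s], 3), "): ",
         "stopping recruitment during an intermediate stage would make later ",
         "stages redundant")
  }
  # recruiting durations: clamp degenerate (non-positive) stages to zero and
  # truncate the final stage at the recruitment stop when one is set
  d_recruit <- pmax(0, durations)
  if (!is.null(spec$recruit_stop))
    d_recruit[s] <- max(0, min(d_recruit[s],
                               spec$recruit_stop - if (s > 1) t_end[s - 1] else 0))
  n_control <- cumsum(spec$accrual * d_recruit)
  stages_df <- data.frame(
    stage = seq_len(s),
    outcome = vapply(stages, `[[`, character(1), "outcome_kind"),
    alpha = spec$alpha, omega = spec$omega,
    delta = vapply(stages, `[[`, numeric(1), "delta"),
    e_control = vapply(stages, `[[`, integer(1), "e_control"),
    e_exp_alt = vapply(stages, `[[`, numeric(1), "e_exp_alt"),
    t_end = t_end, duration = durations,
    n_control = n_control,
    n_total = (1 + spec$allocation) * n_control,
    power_marginal = vapply(stages, `[[`, numeric(1), "power_marginal")
  )
  stages_df$e_total <- stages_df$e_control + stages_df$e_exp_alt
  structure(list(stages = stages_df, spec = spec,
                 total_patients = (1 + spec$allocation) * n_control[s],
                 degenerate = degenerate,
                 degenerate_message = messages),
            class = "tams_design")
}

#' @export
print.tams_design <- function(x, digits = 3, ...) {
  s <- x$spec$n_stages
  cat("Multi-stage lack-of-benefit design (", s, " stage",
      if (s > 1) "s", ")\n", sep = "")
  cat("  HR under H1:", format(x$spec$hr_alt[s]),
      " allocation ratio:", format(x$spec$allocation),
      " control accrual:", paste(format(x$spec$accrual), collapse = "/"),
      "per time-unit\n")
  cat("  hazards (I, D): ", format(x$spec$hazard_I), ", ",
      format(x$spec$hazard_D), "\n\n", sep = "")
  df <- x$stages
  out <- data.frame(stage = df$stage, outcome = df$outcome,
                    alpha = df$alpha, omega = df$omega,
                    delta = round(df$delta, digits),
                    e_control = df$e_control,
                    e_total = round(df$e_total),
                    t_end = round(df$t_end, 2),
                    power = round(df$power_marginal, 4))
  print(out, row.names = FALSE)
  cat("\nTotal patients (both arms):", round(x$total_patients), "\n")
  if (x$degenerate)
    cat("Warning - degenerate design:\n ",
        paste(x$degenerate_message, collapse = "\n  "), "\n")
  invisible(x)
}

#' Summarise a multi-stage design
#'
#' Augments the stage table with overall operating characteristics from
#' [tams_oc()] evaluated at the design's attenuation factor.
#'
#' @param object a `tams_design`.
#' @param ... passed to [tams_oc()].
#' @return An object of class `summary.tams_design`.
#' @export
summary.tams_design <- function(object, ...) {
  oc <- tams_oc(object, ...)
  structure(list(design = object, oc = oc), class = "summary.tams_design")
}

#' @export
print.summary.tams_design <- function(x, ...) {
  print(x$design)
  cat("\n")
  print(x$oc)
  invisible(x)
}

#' @export
coef.tams_design <- function(object, ...) {
  stats::setNames(object$stages$delta,
                  paste0("delta", seq_len(nrow(object$stages))))
}

#' Plot the stopping boundary of a design
#'
#' Draws the critical hazard ratio against cumulative control-arm events as a
#' step function, marking intermediate (I) and definitive (D) looks.
#'
#' @param x a `tams_design`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tams_design <- function(x, ...) {
  df <- x$stages
  graphics::plot(df$e_control, df$delta, type = "s",
                 xlab = "cumulative control-arm events",
                 ylab = "critical hazard ratio",
                 ylim = range(c(df$delta, 1)), ...)
  graphics::points(df$e_control, df$delta,
                   pch = ifelse(df$outcome == "D", 19, 1))
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", pch = c(1, 19), bty = "n",
                   legend = c("intermediate look", "definitive analysis"))
  invisible(x)
}
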