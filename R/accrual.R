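#' Accrual schedule for one trial arm
#'
#' Describes stagewise-uniform patient entry into a single arm: recruitment
#' proceeds at a constant rate within each stage, with rates allowed to differ
#' between stages, and optionally stops altogether at a calendar time
#' `recruit_stop` after which patients already entered remain under follow-up.
#'
#' @param rates numeric vector of non-negative entry rates (patients per
#'   time-unit), one per stage.
#' @param boundaries increasing vector of stage end-times, same length as
#'   `rates`. Beyond the last boundary the last rate is extrapolated (or zero
#'   once `recruit_stop` has passed).
#' @param recruit_stop optional calendar time at which recruitment ceases.
#' @return An object of class `accrual_schedule`.
#' @examples
#' sched <- accrual_schedule(rates = 125, boundaries = 10)
#' events_at(2, sched, hazard = 0.693)
#' @export
accrual_schedule <- function(rates, boundaries, recruit_stop = NULL) {
  stopifnot(length(rates) == length(boundaries), all(rates >= 0),
            all(diff(c(0, boundaries)) > 0))
  if (!is.null(recruit_stop)) {
    stopifnot(is.numeric(recruit_stop), length(recruit_stop) == 1L,
              recruit_stop > 0)
  }
  structure(list(rates = as.numeric(rates),
                 boundaries = as.numeric(boundaries),
                 recruit_stop = recruit_stop),
            class = "accrual_schedule")
}

#' Expected events under uniform entry and exponential survival
#'
#' With patients entering at a uniform rate `r` on (0, t] and failing with
#' constant hazard `hazard`, the expected number of events by time `t` is
#' `r*t - (r/hazard)*(1 - exp(-hazard*t))`.
#'
#' @param rate entry rate (patients per time-unit), one arm.
#' @param hazard exponential event hazard (> 0).
#' @param t elapsed time (>= 0).
#' @return Expected event count (not an integer).
#' @examples
#' expected_events_uniform(100, 0.35, 5)   # about 264
#' @export
expected_events_uniform <- function(rate, hazard, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  stopifnot(rate >= 0, hazard > 0)
  rate * t - (rate / hazard) * (1 - exp(-hazard * t))
}

#' Advance the at-risk/event state across one recruitment interval
#'
#' One step of the fluid (expected-value) recurrence for a memoryless survival
#' distribution: starting from `n_risk` patients at risk and `events`
#' cumulative events, patients enter at rate `rate` for a further duration `d`
#' and fail with constant hazard `hazard`. Existing patients survive the
#' interval with probability `exp(-hazard*d)`; new entries contribute the
#' uniform-entry expectation. Because the exponential distribution is
#' memoryless, time-on-study of the carried-over patients is irrelevant.
#'
#' @param n_risk patients at risk at the start of the interval.
#' @param events cumulative expected events at the start of the interval.
#' @param rate entry rate during the interval.
#' @param hazard exponential event hazard.
#' @param d interval duration (>= 0).
#' @return A list with updated `n_risk` and `events`.
#' @export
advance_state <- function(n_risk, events, rate, hazard, d) {
  if (d < 0) stop("'d' must be non-negative")
  S <- exp(-hazard * d)
  new_events <- rate * d - (rate / hazard) * (1 - S)
  list(n_risk = n_risk * S + (rate / hazard) * (1 - S),
       events = events + n_risk * (1 - S) + new_events)
}

# walk the schedule to time t, returning both N(t) and e(t)
.state_at <- function(t, schedule, hazard) {
  stopifnot(t >= 0)
  b <- schedule$boundaries
  r <- schedule$rates
  ts <- schedule$recruit_stop
  # breakpoints where the entry rate changes, clipped to [0, t]
  cuts <- b[b < t]
  if (!is.null(ts) && ts < t) cuts <- sort(unique(c(cuts, ts)))
  cuts <- c(cuts, t)
  n <- 0; e <- 0; t0 <- 0
  for (t1 in cuts) {
    k <- findInterval(t0, b) + 1L
    rate <- if (k <= length(r)) r[k] else r[length(r)]
    if (!is.null(ts) && t0 >= ts) rate <- 0
    st <- advance_state(n, e, rate, hazard, t1 - t0)
    n <- st$n_risk; e <- st$events; t0 <- t1
  }
  list(n_risk = n, events = e)
}

#' Expected cumulative events at a calendar time
#'
#' Piecewise evaluation of the expected-event recurrence through whole stages
#' plus a partial step. After `recruit_stop` the entry rate is zero and the
#' at-risk pool decays exponentially, so events converge to the number of
#' patients recruited. Times beyond the last stage boundary extrapolate with
#' the last rate (or zero after `recruit_stop`).
#'
#' @param t calendar time (>= 0).
#' @inheritParams time_for_events
#' @return Expected cumulative event count at `t`.
#' @export
events_at <- function(t, schedule, hazard) {
  vapply(t, function(ti) .state_at(ti, schedule, hazard)$events, numeric(1))
}

#' Patients at risk at a calendar time
#'
#' @inheritParams events_at
#' @return Expected number of patients under follow-up and event-free at `t`.
#' @export
at_risk_at <- function(t, schedule, hazard) {
  vapply(t, function(ti) .state_at(ti, schedule, hazard)$n_risk, numeric(1))
}

#' Calendar time at which an expected event target is reached
#'
#' Inverts [events_at()] by Newton-Raphson, using the identity that the event
#' intensity is hazard times the number at risk, e'(t) = hazard * N(t). The
#' starting value is `t_floor` plus half the median survival time; any Newton
#' step that leaves the bracket (or fails to shrink it) falls back to
#' bisection. Convergence tolerance is 1e-6 events.
#'
#' @param e_target expected cumulative events to reach (> 0).
#' @param schedule an [accrual_schedule()].
#' @param hazard exponential event hazard.
#' @param t_floor lower bound for the solution, e.g. the end of the previous
#'   stage. Default 0.
#' @return Calendar time `t` with `events_at(t) == e_target` to 1e-6.
#' @export
time_for_events <- function(e_target, schedule, hazard, t_floor = 0) {
  stopifnot(e_target > 0, t_floor >= 0)
  if (!is.null(schedule$recruit_stop)) {
    recruited <- cumulative_recruits(schedule$recruit_stop, schedule)
    if (e_target >= recruited) {
      stop("design infeasible: event target ", e_target,
           " can never be reached with only ", round(recruited, 2),
           " patients recruited before the recruitment stop")
    }
  }
  lo <- t_floor
  hi <- NA_real_
  t <- t_floor + 0.5 * log(2) / hazard
  for (iter in 1:200) {
    st <- .state_at(t, schedule, hazard)
    g <- st$events - e_target
    if (abs(g) < 1e-6) return(t)
    if (g < 0) lo <- max(lo, t) else hi <- if (is.na(hi)) t else min(hi, t)
    step <- g / (hazard * st$n_risk)
    t_new <- t - step
    if (!is.finite(t_new) || t_new <= lo || (!is.na(hi) && t_new >= hi)) {
      t_new <- if (is.na(hi)) max(2 * t, t + log(2) / hazard) else (lo + hi) / 2
    }
    t <- t_new
  }
  stop("event-time inversion did not converge for target ", e_target)
}

#' Cumulative patients recruited to one arm by a calendar time
#'
#' @inheritParams events_at
#' @return Number of patients entered on (0, t], honouring `recruit_stop`.
#' @export
cumulative_recruits <- function(t, schedule) {
  b <- c(0, schedule$boundaries)
  r <- schedule$rates
  ts <- schedule$recruit_stop
  tot <- 0
  for (i in seq_along(r)) {
    hi <- if (i < length(r)) b[i + 1L] else max(t, b[i + 1L])
    seg <- min(t, hi, if (is.null(ts)) Inf else ts) - min(b[i], t)
    if (seg > 0) tot <- tot + r[i] * seg
  }
  tot
}

#' Total trial size under an allocation ratio
#'
#' Patients recruited to both arms by `t_stop`: `(1 + A)` times the control-arm
#' recruits, the experimental arm entering at `A` times the control rate.
#'
#' @param schedule control-arm [accrual_schedule()].
#' @param allocation allocation ratio A (experimental per control patient).
#' @param t_stop calendar time at which recruitment ends.
#' @return Total patient count (both arms).
#' @export
total_patients <- function(schedule, allocation, t_stop) {
  (1 + allocation) * cumulative_recruits(t_stop, schedule)
}
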