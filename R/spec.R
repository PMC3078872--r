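#' Validated parameter set for a multi-stage design
#'
#' Bundles and checks the design parameters used by [tams_design()]. Most
#' users call [tams_design()] directly; `tams_spec()` is exposed for config
#' parsing and programmatic construction.
#'
#' Validation rules: the stage significance levels must be strictly
#' descending (otherwise later stages are redundant); all hazards, rates and
#' the allocation ratio must be positive; the alternative hazard ratio must
#' lie below the null at every stage. An intermediate-outcome hazard below
#' the definitive hazard draws a warning (the intermediate event should occur
#' at least as often as the definitive one), and more than six stages draws a
#' warning (rarely of practical value).
#'
#' @inheritParams tams_design
#' @return A list of class `tams_spec` with normalised fields: per-stage
#'   vectors `alpha`, `omega`, `hr_null`, `hr_alt`, `accrual` (control-arm
#'   scale), scalars `allocation`, `hazard_I`, `hazard_D`, `attenuation`,
#'   `power_tol`, optional `recruit_stop`, plus `n_stages` and the
#'   convenience flag `single_outcome` (`hazard_I == hazard_D`).
#' @export
tams_spec <- function(alpha, omega, hr_alt, hr_null = 1, allocation = 1,
                      accrual, accrual_scope = c("control", "total"),
                      hazard_I = NULL, hazard_D = NULL,
                      median_I = NULL, median_D = NULL,
                      recruit_stop = NULL, attenuation = 0.6,
                      power_tol = 2e-4) {
  accrual_scope <- match.arg(accrual_scope)
  s <- length(alpha)
  stopifnot(s >= 1, length(omega) == s)
  if (s > 1 && any(diff(alpha) >= 0))
    stop("stage significance levels must be strictly descending; ",
         "non-descending values make some stages redundant")
  if (any(alpha <= 0 | alpha >= 1) || any(omega <= 0 | omega >= 1))
    stop("'alpha' and 'omega' must lie strictly in (0, 1)")
  if (s > 6)
    warning("more than 6 stages is rarely of practical value")

  rep_s <- function(x, name) {
    if (length(x) == 1L) rep(x, s)
    else if (length(x) == s) as.numeric(x)
    else stop("'", name, "' must have length 1 or ", s)
  }
  hr_null <- rep_s(hr_null, "hr_null")
  hr_alt <- rep_s(hr_alt, "hr_alt")
  if (any(hr_null <= 0) || any(hr_alt <= 0))
    stop("hazard ratios must be positive")
  if (any(hr_alt >= hr_null))
    stop("'hr_alt' must be smaller than 'hr_null' at every stage")
  stopifnot(allocation > 0)

  accrual <- rep_s(accrual, "accrual")
  if (any(accrual <= 0)) stop("accrual rates must be positive")
  if (accrual_scope == "total") accrual <- accrual / (1 + allocation)

  pick_hazard <- function(hazard, med, name) {
    if (is.null(hazard)) {
      if (is.null(med)) stop("supply either 'hazard_", name,
                             "' or 'median_", name, "'")
      hazard <- log(2) / med
    }
    if (hazard <= 0) stop("'hazard_", name, "' must be positive")
    hazard
  }
  hazard_D <- pick_hazard(hazard_D, median_D, "D")
  hazard_I <- if (s == 1 && is.null(hazard_I) && is.null(median_I)) hazard_D
              else pick_hazard(hazard_I, median_I, "I")
  if (hazard_I < hazard_D)
    warning("intermediate-outcome hazard is below the definitive-outcome ",
            "hazard; intermediate events should occur at least as frequently")
  stopifnot(attenuation > 0, attenuation <= 1, power_tol >= 0)

  structure(list(n_stages = s, alpha = as.numeric(alpha),
                 omega = as.numeric(omega), hr_null = hr_null,
                 hr_alt = hr_alt, allocation = allocation,
                 accrual = accrual, hazard_I = hazard_I, hazard_D = hazard_D,
                 recruit_stop = recruit_stop, attenuation = attenuation,
                 power_tol = power_tol,
                 single_outcome = isTRUE(all.equal(hazard_I, hazard_D))),
            class = "tams_spec")
}

#' @export
print.tams_spec <- function(x, ...) {
  cat("tams_spec:", x$n_stages, "stages\n")
  cat("  alpha:", paste(x$alpha, collapse = ", "), "\n")
  cat("  omega:", paste(x$omega, collapse = ", "), "\n")
  cat("  HR (null/alt):", paste(x$hr_null, collapse = ","), "/",
      paste(x$hr_alt, collapse = ","), "\n")
  cat("  allocation:", x$allocation,
      " accrual (control):", paste(x$accrual, collapse = ", "), "\n")
  cat("  hazards I/D:", x$hazard_I, "/", x$hazard_D, "\n")
  if (!is.null(x$recruit_stop)) cat("  recruitment stops at:", x$recruit_stop, "\n")
  invisible(x)
}
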