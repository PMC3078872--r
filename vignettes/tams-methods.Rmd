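---
title: "Multi-stage lack-of-benefit designs: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage lack-of-benefit designs: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tams)
```

This vignette is the package's account of the statistical method it
implements, the assumptions behind it, the numerical choices made where the
design was genuinely open, and what the tests do and do not establish.

## 1. The design problem

A two-arm multi-stage (TAMS) trial compares an experimental treatment `E`
with control `C` on time-to-event outcomes and stops recruitment early if
`E` fails to show a predefined advantage. Stages `1, ..., s - 1` analyse an
*intermediate* outcome `I` (e.g. progression-free survival) at relaxed
one-sided significance levels `alpha_1 > alpha_2 > ... ` and high powers
`omega_i` (0.95 is typical); stage `s` analyses the *definitive* outcome `D`
(e.g. overall survival) at a conventional level such as 0.025 with power
0.9. The `I`-outcome must occur no later and at least as often as `D` and
lie on its causal pathway, but it need not be a formal surrogate: a null
effect on `I` must imply a null effect on `D`, while the converse is not
required. A multi-arm (MAMS) trial is treated as a set of such pairwise
comparisons; no familywise adjustment across arms is attempted here.

The stopping rule is one-sided and non-binding in the benefit direction:
at stage `i` the trial *continues* if the estimated hazard ratio (E vs C)
does not exceed the critical value `delta_i`. Ties at the boundary have
probability zero; we resolve them by continuing, so the stage level is not
exceeded.

## 2. Critical values and event targets

The estimated log hazard ratio at stage `i` is modelled as normal with mean
`log Delta_i` and variance approximated by `(1 + 1/A)/e_i` under the null
(`e_i` = cumulative control-arm events on the stage's outcome, `A` =
allocation ratio) and by `1/e_i + 1/e*_i` under the alternative, where
`e*_i` is the expected experimental-arm event count when the control arm
reaches `e_i`. The two-arm reciprocal form matters under the alternative
because an effective treatment generates fewer events. The boundary solves
the stage level exactly:

    log delta_i = log HR0_i + qnorm(alpha_i) * sigma0_i,

so `delta_i = HR0_i` whenever `alpha_i = 0.5`. The attained marginal power
is `Phi((log delta_i - log HR1_i)/sigma1_i)`.

Event targets are integers found by search, not by a closed form: starting
from the classical two-group approximation
`ceiling((1 + 1/A)(qnorm(omega) - qnorm(alpha))^2 / log(HR0/HR1)^2)`
(which undershoots, because it uses the null variance), the target is
incremented by single events — guaranteeing minimality — until the attained
power reaches the nominal one. Each candidate requires the stage end-time
`t_i` (section 3) and `e*_i` at that time.

**Power tolerance.** The iteration accepts a candidate when the attained
power reaches `omega_i - power_tol` with `power_tol = 2e-4` by default.
Several published stage targets for this class of designs correspond to
attained powers that fall short of nominal by one to two units in the fourth
decimal; the tolerance reproduces the reference software's convergence
behaviour at those knife-edge cases. It was fixed once, from the published
design tables, before the package's tests were written; `power_tol = 0`
gives the strict rule and changes a handful of borderline targets by one
event.

**Stage order and outcome bookkeeping.** Looks are indexed by cumulative
*control-arm* events on the triggering outcome. Because the control arm is
untouched by treatment, stage times are identical under the null and the
alternative. When `I` and `D` coincide (one outcome for all stages, a
supported special case) the final target is clamped above the previous one;
a clamp forced this way flags the design as degenerate (a near-zero-length
stage), which is reported, not fatal.

## 3. Accrual and timing calculus

Timing assumes exponential event times and stagewise-uniform accrual. Both
assumptions affect *only* the calendar timeline: the event targets and
boundaries depend on `(alpha, omega, HR0, HR1, A)` and on `e*_i/e_i`, so a
misspecified survival shape perturbs `t_i` but not the decision structure.

With entry rate `r` on `(0, t]` and hazard `lambda`, expected events are
`r t - (r/lambda)(1 - exp(-lambda t))`. Stagewise rates are handled by a
recurrence over stages in `(N(t), e(t))` (at-risk, cumulative events),
licensed by the memorylessness of the exponential: survivors of earlier
stages can be aged forward without tracking entry times. Conservation
(`N + e` = recruits) holds exactly and is tested. An optional recruitment
stop `t*` — only sensible inside the final stage, and rejected elsewhere —
zeroes the entry rate thereafter; events then converge to the number
recruited.

The inverse problem (time at which `e` expected events are reached) is
solved by Newton-Raphson using the identity `e'(t) = lambda * N(t)`,
starting at the previous stage end plus half a median, with a bisection
fallback whenever a Newton step leaves the feasible bracket; convergence
tolerance is `1e-6` events. An unreachable target under a recruitment stop
raises an explicit infeasibility error.

One behavioural consequence worth knowing: a recruitment stop *lengthens*
the final stage but can *shrink* its event target by a few events, because
the extra follow-up matures the experimental arm and raises the attained
power per control event. The iterative rule is applied consistently in both
situations.

## 4. Correlations and operating characteristics

The stagewise log hazard-ratio estimates are treated as jointly normal. For
looks on a common outcome the correlation is `sqrt(e_i/e_j)` — exact for
the event-count-ratio estimator under the null with Poisson entry, and an
excellent approximation for the partial-likelihood estimator (the package's
simulator reproduces it to Monte-Carlo precision). Between an intermediate
look and the definitive stage the correlation is attenuated,
`R_is = c * sqrt(e_i/e_s)` with `c` in (0, 1]; `c = 1` recovers the
single-outcome case.

Overall significance `alpha` and power `omega` are lower orthant
probabilities of the `s`-dimensional standard normal at
`qnorm(alpha_i)` resp. `qnorm` of the *attained* marginal powers — using
attained rather than nominal powers is required to reproduce the published
conditional powers, which exceed the nominal 0.95 because event targets are
integers. Conditional quantities are ratios of successive joint
probabilities and telescope to the overall ones (tested to `1e-6`).

**Bounds over `c`.** Because the lower orthant probability is increasing in
every correlation (Slepian's inequality), the minimum over `c` sits at
`c = 0`, where the final stage is independent of the intermediate block and
the probability factorises as `alpha_I * alpha_s`; the maximum sits at the
largest `c <= 1` that keeps `R` positive semi-definite (usually 1). Some
descriptions of this method state the opposite mapping; the direction
implemented here is forced by Slepian monotonicity and is consistent with
the attenuation sensitivity analysis itself, where `alpha` roughly doubles
as `c` goes from 0.4 to 0.8 while `omega` moves little. Underestimating `c`
is therefore the conservative direction for power statements.

**Defaults.** `c = 0.6` by default — simulation-based estimates for
composite intermediate outcomes cluster around 0.63-0.73, and a rule of
thumb maps a known fixed-time cross-outcome correlation `rho_ID` to
`c = min(1, 1.1 * rho_ID)` (exposed as `c_from_rho()`, flagged heuristic).
`tams_oc_sensitivity()` reports `alpha(c)`, `omega(c)` over `[0.4, 0.8]`,
the range we consider plausible. Supplied (e.g. empirically estimated)
cross-outcome correlations override the analytic entries; if the completed
matrix loses positive semi-definiteness it is projected to the nearest PSD
correlation matrix by eigenvalue clipping, with a message.

Orthant probabilities use Miwa's deterministic recursive integration
(`mvtnorm`), so repeated runs give identical values; a `1e-8` ridge guards
exactly singular matrices. The deterministic choice is deliberate:
acceptance checks compare these numbers at `1e-3` precision and must not
carry quasi-Monte-Carlo jitter.

## 5. The correlated outcome generator

The simulator needs patient-level pairs: a death time `Y` and a composite
intermediate time (progression *or* death) that is marginally exponential
and positively dependent on `Y`. Construction: `(U, V)` standard bivariate
normal with correlation `rho` (default 0.6); `X = -log(pnorm(U))/lambda_x`,
`Y = -log(pnorm(V))/lambda_D` (exact exponential marginals);
`Z = min(X, Y)`. A patient may die before progression is detected, so
`Z = Y` on those realisations is natural. Because the minimum of
*correlated* exponentials is not exponential, two calibrations are applied:

1. **Hazard matching.** The latent progression hazard `lambda_x` is solved
   (monotone bisection with common random numbers) so that the Monte-Carlo
   hazard of `Z` — the reciprocal of its sample mean — equals the specified
   intermediate hazard `lambda_I`. At `rho = 0` the exact solution
   `lambda_I - lambda_D` is returned directly.
2. **Quantile correction.** A monotone quantile map estimated from a large
   calibration sample (default `1e6` draws, 16384 stored knots, linear tail
   extension) carries `Z` to the exponential(`lambda_I`) scale, giving the
   corrected `Z'` used by the simulator. The map preserves patient ordering
   and leaves an already-exponential composite essentially unchanged. A
   three-parameter parametric correction on the normal scale could be used
   instead; the empirical map was chosen because it achieves the stated goal
   (exact exponential marginal) by construction and is directly testable —
   the post-correction Kolmogorov-Smirnov distance drops below the
   pre-correction one and the composite hazard lands within 1% of target.

Treatment acts by proportional hazards on both outcomes: equal hazard
ratios rescale the calibrated model exactly; unequal ones re-solve and
recalibrate.

## 6. The trial simulator

Patients enter each arm stagewise-uniformly by default (matching the fluid
timing calculus) or by Poisson processes (the assumption under which the
square-root correlation is exact); rates are `r_i` control and `A r_i`
experimental, until the planned end of recruitment. Looks are event-driven:
look `i` occurs at the calendar time of the `e_i`-th control-arm event on
the triggering outcome, never at the planned `t_i`. Analyses censor
everyone alive at the look and exclude patients not yet entered. The
default estimator maximises the Cox partial likelihood (Breslow ties); an
event-count-ratio estimator `O_i/(A e_i)` is provided for correlation
studies, where it is the quantity the analytic `sqrt(e_i/e_j)` describes.
An arm with zero events resolves the look by sign. Replicate seeds are
derived from the master seed, so results are reproducible and independent
of chunking.

Summaries: stagewise conditional pass probabilities with binomial standard
errors on the conditioning counts, overall pass probability, empirical
cross-stage correlation matrix, per-stage attenuation estimates
`R_is / sqrt(e_i/e_s)`, the fixed-time cross-outcome correlation, and the
mean information fraction at stopping (control-arm definitive events at
stop over the definitive target, counting full-course replicates at 1.0 —
the averaging convention is ours; the quantity is used qualitatively only).

Single-stage bias diagnostics standardise the log hazard-ratio estimate by
the design variances; their means sit at the design z-values and their
standard deviations within a few percent of 1. The fine structure of those
few-percent departures is sensitive to simulator conventions (event-driven
versus calendar-time analysis, accrual); with event-driven looks the
conditioning on the `e`-th control event slightly deflates the null-side
standard deviation. We report the statistics and assert only the bounded
departure.

## 7. What the tests show, and what they do not

The test suite verifies: the printed stage tables of the reference designs
(event targets, boundaries, timings, patient totals); the analytic
operating characteristics at three-decimal precision; agreement of the
simulator's conditional and overall pass probabilities with both the
analytic model and published 50,000-replicate values at Monte-Carlo
precision (10,000 replicates here; one published stage-1 cell is printed
inconsistently across its three appearances and is checked against the set);
recovery of the square-root correlation structure; exactness of the
generator's marginals (Kolmogorov-Smirnov); parameter recovery of the Cox
estimator against an independently coded partial-likelihood oracle; and the
structural properties — minimality of event targets, telescoping
conditionals, conservation of patients, Newton round-trips, Slepian
monotonicity in `c`, and the `alpha <= alpha_s`, `omega <= omega_s` bounds.

None of this shows that real trials behave this way. The generator emulates
exponential, proportional-hazards, dropout-free data with a
time-constant copula dependence; real data have non-exponential baselines
(which distort the planned calendar times, though not the event targets),
non-proportional hazards (which the method does not address), loss to
follow-up, delayed ascertainment of intermediate events at scheduled visits,
and accrual that ramps up rather than jumping between stagewise constants.
The attenuation factor `c` in any real application is an estimate; the
sensitivity report over `[0.4, 0.8]` should accompany any design summary.

Problem sizes were chosen to keep the full suite comfortably
reproducible at a desk: 10,000 replicates for operating-characteristic
checks (standard errors around 0.003-0.005), 5,000 for correlation
recovery, calibration samples of `1e5`-`5e5` in tests and `1e6` by default
in production use.

## 8. Known limitations

- Exponential survival only; piecewise-exponential or transformed-baseline
  extensions would change the timing calculus (section 3) but not the
  event/boundary logic.
- Pairwise comparisons only: no shared-control multiplicity adjustment, no
  familywise error control across arms of a MAMS trial.
- No stopping for benefit; the boundaries screen solely for lack of
  benefit.
- The normal approximation for the log hazard ratio is least accurate at
  the smallest event targets (first looks of designs with `alpha_1 = 0.5`),
  where simulated pass probabilities exceed nominal by up to about one
  percentage point — visible in the validation tables and tolerated there.
- `c` is assumed stage-constant; simulation estimates vary by roughly
  +/- 0.05 across stages.
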