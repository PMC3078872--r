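test_that("variance approximations match their closed forms", {
  expect_equal(variance_null(264, 1), 2 / 264)
  expect_equal(variance_null(140, 1), 0.0142857, tolerance = 1e-5)
  # single-arm limit: infinite allocation leaves 1/e
  expect_equal(variance_null(100, 1e12), 1 / 100, tolerance = 1e-9)
  expect_equal(variance_alt(264, 222), 1 / 264 + 1 / 222)
  expect_equal(variance_alt(73, 60), 0.030365, tolerance = 1e-4)
  expect_equal(variance_alt(50, 50), 2 / 50)
  expect_error(variance_null(0, 1), "positive")
  expect_error(variance_alt(10, -1), "positive")
})

test_that("critical hazard ratios reproduce the printed boundary column", {
  expect_equal(critical_hr(0.5, 0.123), 1)
  expect_equal(critical_hr(0.025, sqrt(2 / 262)), 0.843, tolerance = 5e-4)
  expect_equal(critical_hr(0.25, sqrt(2 / 140)), 0.923, tolerance = 5e-4)
  # boundary at the alternative gives power one half
  expect_equal(attained_power(0.75, 0.75, 0.2), 0.5)
  expect_equal(attained_power(critical_hr(0.025, sqrt(2 / 264)), 0.75,
                              sqrt(1 / 264 + 1 / 222)), 0.90, tolerance = 5e-3)
  expect_equal(attained_power(1, 0.75, sqrt(1 / 73 + 1 / 60)), 0.95,
               tolerance = 5e-3)
})

test_that("the closed-form starting event count matches hand arithmetic", {
  # 2*(qnorm(.9) - qnorm(.025))^2 / log(4/3)^2 = 253.93, rounded up
  expect_equal(initial_events(0.025, 0.9, 1, 0.75, 1), 254)
  expect_equal(initial_events(0.5, 0.5001, 1, 0.75, 1), 1)  # clamped floor
  expect_equal(initial_events(0.5, 0.95, 1, 0.75, 0.5), 99)
  expect_error(initial_events(0.025, 0.9, 1, 1.1, 1), "smaller")
})

test_that("the solved designs reproduce the published stage tables", {
  d <- tams_design(alpha = c(0.5, 0.25, 0.125, 0.025),
                   omega = c(0.95, 0.95, 0.95, 0.9), hr_alt = 0.75,
                   accrual = 100, hazard_I = 0.69, hazard_D = 0.35)
  expect_equal(d$stages$e_control, c(73, 139, 198, 264))
  expect_equal(round(d$stages$e_total[4]), 486)
  expect_equal(d$stages$t_end[4], 5.0, tolerance = 0.1)
  expect_equal(d$total_patients, 1000, tolerance = 5)

  d2 <- tams_design(alpha = c(0.5, 0.25, 0.125, 0.025),
                    omega = c(0.95, 0.95, 0.95, 0.9), hr_alt = 0.75,
                    allocation = 0.5, accrual = 200, accrual_scope = "total",
                    hazard_I = 0.69, hazard_D = 0.35)
  expect_equal(d2$stages$e_control[4], 399)
  expect_equal(round(d2$stages$e_total[4]), 568)

  d3 <- design_3stage()
  expect_equal(d3$stages$e_control, c(73, 140, 264))
  expect_equal(d3$stages$t_end, c(1.53, 2.27, 4.37), tolerance = 0.02)

  d4 <- tams_design(alpha = c(0.5, 0.25, 0.1, 0.025),
                    omega = c(0.95, 0.95, 0.95, 0.9), hr_alt = 0.75,
                    accrual = 125, hazard_I = 0.693, hazard_D = 0.693)
  expect_equal(d4$stages$e_control, c(73, 140, 217, 262))
  expect_equal(round(d4$stages$delta, 3), c(1.000, 0.923, 0.884, 0.843))
})

test_that("a one-stage design reduces to a conventional one-look trial", {
  d <- design_single()
  expect_equal(nrow(d$stages), 1L)
  expect_identical(d$stages$outcome, "D")
  e <- d$stages$e_control
  # attained power at the integer target brackets the nominal power
  expect_gte(d$stages$power_marginal, 0.9 - d$spec$power_tol)
  sched <- accrual_schedule(250, 100)
  t_dec <- time_for_events(e - 1, sched, log(2))
  e_exp <- events_at(t_dec, sched, 0.75 * log(2))
  expect_lt(attained_power(critical_hr(0.025, sqrt(variance_null(e - 1, 1))),
                           0.75, sqrt(variance_alt(e - 1, e_exp))), 0.9)
})

test_that("event targets are minimal: one fewer event loses the power", {
  d <- design_3stage()
  spec <- d$spec
  for (i in seq_len(spec$n_stages)) {
    e <- d$stages$e_control[i]
    hazard <- if (i < spec$n_stages) spec$hazard_I else spec$hazard_D
    sched <- accrual_schedule(125, 100)
    t_dec <- time_for_events(e - 1, sched, hazard)
    e_exp <- events_at(t_dec, accrual_schedule(125, 100),
                       spec$hr_alt[i] * hazard)
    pow <- attained_power(critical_hr(spec$alpha[i],
                                      sqrt(variance_null(e - 1, 1))),
                          spec$hr_alt[i], sqrt(variance_alt(e - 1, e_exp)))
    expect_lt(pow, spec$omega[i] - spec$power_tol)
  }
})

test_that("boundary equals the null hazard ratio exactly when alpha is 0.5", {
  d <- design_3stage()
  expect_equal(d$stages$delta[1], 1)
})

test_that("event targets respond monotonically to power and significance", {
  base <- design_single()$stages$e_control
  for (w in c(0.91, 0.93, 0.95)) {
    e_w <- tams_design(alpha = 0.025, omega = w, hr_alt = 0.75,
                       accrual = 250, median_D = 1)$stages$e_control
    expect_gte(e_w, base)
    base <- e_w
  }
  e_prev <- Inf
  for (a in c(0.01, 0.05, 0.1)) {
    e_a <- tams_design(alpha = a, omega = 0.9, hr_alt = 0.75,
                       accrual = 250, median_D = 1)$stages$e_control
    expect_lte(e_a, e_prev)
    e_prev <- e_a
  }
})

test_that("rescaling time units leaves events and boundaries unchanged", {
  k <- 2.5
  d <- design_3stage()
  dk <- tams_design(alpha = c(0.5, 0.25, 0.025), omega = c(0.95, 0.95, 0.9),
                    hr_alt = 0.75, accrual = 125 * k,
                    hazard_I = log(2) * k, hazard_D = log(2) / 2 * k)
  expect_equal(dk$stages$e_control, d$stages$e_control)
  expect_equal(dk$stages$delta, d$stages$delta, tolerance = 1e-9)
  expect_equal(dk$stages$t_end, d$stages$t_end / k, tolerance = 1e-6)
})

test_that("expected experimental events match patient-level simulation", {
  d <- design_3stage()
  spec <- d$spec
  i <- 2
  t_i <- d$stages$t_end[i]
  lam_e <- spec$hr_alt[i] * spec$hazard_I
  set.seed(31)
  nrep <- 400
  counts <- replicate(nrep, {
    n <- rpois(1, 125 * t_i)
    entry <- runif(n, 0, t_i)
    sum(rexp(n, lam_e) <= t_i - entry)
  })
  se <- sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - d$stages$e_exp_alt[i]), 2 * se)
})

test_that("invalid parameter sets are rejected with useful messages", {
  expect_error(tams_design(alpha = c(0.25, 0.5), omega = c(0.95, 0.9),
                           hr_alt = 0.75, accrual = 100, median_I = 1,
                           median_D = 2),
               "descending")
  expect_error(tams_design(alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
                           hr_alt = 1.2, accrual = 100, median_I = 1,
                           median_D = 2),
               "smaller")
  expect_warning(tams_design(alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
                             hr_alt = 0.75, accrual = 100, median_I = 3,
                             median_D = 2),
                 "at least as frequently")
  expect_error(tams_design(alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
                           hr_alt = 0.75, accrual = 100, median_I = 1,
                           median_D = 2, recruit_stop = 0.5),
               "final stage")
})

test_that("stopping recruitment early lengthens the final stage", {
  d <- design_3stage()
  t2 <- d$stages$t_end[2]
  ts <- t2 + 0.3
  ds <- design_3stage(recruit_stop = ts)
  expect_equal(ds$stages$e_control[1:2], d$stages$e_control[1:2])
  # the longer follow-up matures the experimental arm, so the final event
  # target cannot grow (and may shrink slightly)
  expect_lte(ds$stages$e_control[3], d$stages$e_control[3])
  expect_gt(ds$stages$t_end[3], d$stages$t_end[3])
  expect_lt(ds$total_patients, d$total_patients)
  expect_equal(ds$total_patients, 2 * 125 * ts, tolerance = 1e-6)
})

test_that("a forced non-increasing event sequence flags the design degenerate", {
  d <- suppressMessages(
    tams_design(alpha = c(0.1, 0.05, 0.025), omega = c(0.95, 0.95, 0.9),
                hr_alt = 0.75, accrual = 125,
                hazard_I = 0.693, hazard_D = 0.693))
  expect_true(d$degenerate)
  expect_match(paste(d$degenerate_message, collapse = " "), "zero length")
  expect_true(all(diff(d$stages$e_control) > 0))
})

test_that("design methods print, summarise and expose coefficients", {
  d <- design_3stage()
  expect_output(print(d), "Multi-stage")
  expect_named(coef(d), c("delta1", "delta2", "delta3"))
  s <- summary(d)
  expect_s3_class(s, "summary.tams_design")
  expect_output(print(s), "Overall")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(d))
})
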