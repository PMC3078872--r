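test_that("the partial-likelihood estimate matches an independent implementation", {
  set.seed(21)
  n <- 200
  arm <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.5 * exp(log(0.7) * arm))
  status <- as.integer(time <= 2)
  time <- pmin(time, 2)
  fit <- estimate_loghr(time, status, arm)
  expect_equal(fit$loghr, oracle_cox_loghr(time, status, arm),
               tolerance = 1e-4)
  # and agrees with the formula interface of the survival package
  cx <- survival::coxph(survival::Surv(time, status) ~ arm,
                        ties = "breslow")
  expect_equal(fit$loghr, unname(coef(cx)), tolerance = 1e-8)
})

test_that("label permutation negates the estimate and empty arms resolve by sign", {
  set.seed(22)
  n <- 300
  time <- rexp(n); status <- rbinom(n, 1, 0.8); arm <- rbinom(n, 1, 0.5)
  f1 <- estimate_loghr(time, status, arm)
  f2 <- estimate_loghr(time, status, 1 - arm)
  expect_equal(f1$loghr, -f2$loghr, tolerance = 1e-8)
  expect_identical(estimate_loghr(time, status * (arm == 0), arm)$loghr, -Inf)
  expect_identical(estimate_loghr(time, status * (arm == 1), arm)$loghr, Inf)
})

test_that("true hazard ratios are recovered at the looks", {
  d <- design_single(accrual = 500)
  set.seed(23)
  reps <- replicate(60, simulate_trial(d, hr_I = 0.75)$loghr)
  expect_lt(abs(mean(reps) - log(0.75)), 3 * sd(reps) / sqrt(60))
})

test_that("stage-1 pass probability under the null matches the boundary level", {
  d <- design_3stage()
  set.seed(24)
  m <- outcome_model(lambda_D = d$spec$hazard_D, lambda_I = d$spec$hazard_I,
                     rho = 0.6, n_cal = 1e5)
  s0 <- tams_simulate(d, nsim = 1500, hr_I = 1, model = m, seed = 25)
  p1 <- s0$pass_conditional[1]
  expect_lt(abs(p1 - 0.5), 3 * s0$se_conditional[1])
  # conditional probabilities multiply to the overall pass rate
  reached <- s0$n_reached
  expect_equal(prod(s0$pass_conditional), s0$overall,
               tolerance = 3 / min(reached))
})

test_that("overwhelming benefit passes every stage", {
  d <- design_single(accrual = 500)
  set.seed(26)
  s <- tams_simulate(d, nsim = 30, hr_I = 1e-3)
  expect_equal(s$overall, 1)
})

test_that("replicates are reproducible from the master seed", {
  d <- design_single()
  a <- tams_simulate(d, nsim = 20, hr_I = 0.75, seed = 27)
  b <- tams_simulate(d, nsim = 20, hr_I = 0.75, seed = 27)
  expect_identical(a$loghr, b$loghr)
  expect_identical(a$pass, b$pass)
})

test_that("the count-ratio estimator reproduces the analytic correlation structure", {
  d <- tams_design(alpha = c(0.5, 0.25, 0.1, 0.025),
                   omega = c(0.95, 0.95, 0.95, 0.9), hr_alt = 0.75,
                   accrual = 125, hazard_I = 0.693, hazard_D = 0.693)
  cc <- estimate_cross_correlation(d, nsim = 1500, hr_I = 1,
                                   arrivals = "poisson",
                                   estimator = "counts", seed = 28,
                                   use_log = FALSE)
  e <- d$stages$e_control
  th <- outer(e, e, function(a, b) sqrt(pmin(a, b) / pmax(a, b)))
  se <- 1 / sqrt(cc$n_used)
  expect_lt(max(abs(cc$R - th)), 3 * se)
  expect_true(all(is.na(cc$c_hat)))
})

test_that("the attenuation factor estimated from simulation is plausible", {
  d <- design_3stage()
  set.seed(29)
  m <- outcome_model(lambda_D = d$spec$hazard_D, lambda_I = d$spec$hazard_I,
                     rho = 0.6, n_cal = 1e5)
  cc <- estimate_cross_correlation(d, nsim = 400, hr_I = 1, model = m,
                                   arrivals = "poisson", estimator = "cox",
                                   seed = 30, fixed_time_rho = TRUE)
  expect_true(all(cc$c_hat > 0.5 & cc$c_hat < 0.85))
  expect_true(all(cc$rho_ID > 0.4 & cc$rho_ID < 0.85))
})

test_that("information at stopping is lower with a faster intermediate outcome", {
  a4 <- c(0.5, 0.25, 0.1, 0.025); w4 <- c(0.95, 0.95, 0.95, 0.9)
  d_id <- tams_design(alpha = a4, omega = w4, hr_alt = 0.75, accrual = 125,
                      hazard_I = 0.347, hazard_D = 0.347)
  d_iD <- tams_design(alpha = a4, omega = w4, hr_alt = 0.75, accrual = 125,
                      hazard_I = 0.693, hazard_D = 0.347)
  set.seed(31)
  m <- outcome_model(lambda_D = 0.347, lambda_I = 0.693, rho = 0.6,
                     n_cal = 1e5)
  s_id <- tams_simulate(d_id, nsim = 400, hr_I = 1, seed = 32)
  s_iD <- tams_simulate(d_iD, nsim = 400, hr_I = 1, model = m, seed = 33)
  expect_lt(s_iD$info_fraction, s_id$info_fraction)
})

test_that("single-stage bias diagnostics show the documented variance pattern", {
  di <- diagnostics_bias(alpha_grid = c(0.025), omega_grid = c(0.9, 0.99),
                         nsim = 4000, seed = 34)
  # the standardised statistics are near-standard-normal: their means sit at
  # the design z-values and any variance-approximation bias stays below the
  # few-percent level
  expect_lt(max(abs(di$mean_A1 - di$z_alpha)), 0.05)
  expect_lt(max(abs(di$mean_B1 - di$z_omega)), 0.05)
  expect_lt(max(abs(di$sd_A1 - 1)), 0.05)
  expect_lt(max(abs(di$sd_B1 - 1)), 0.05)
})
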