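test_that("hazard evaluation is multiplicative in baseline and covariates", {
  traj <- new_trajectory(c(0, 500), c(50, 50))
  null <- hazard_params(0, 0, c(0, 500), c(0.001, 0.002))
  expect_equal(hazard_at(100, traj, 3, null), 0.001)
  expect_equal(hazard_at(700, traj, 3, null), 0.002)

  # unit covariate with beta = log 2 doubles the hazard
  pr <- hazard_params(log(2), 0, 0, 0.01)
  t1 <- new_trajectory(0, 1)
  t0 <- new_trajectory(0, 0)
  expect_equal(hazard_at(10, t1, 0, pr) / hazard_at(10, t0, 0, pr), 2)

  pw <- hazard_params(0.01, 0, c(0, 500), c(0.001, 0.002))
  expect_equal(hazard_at(600, traj, 0, pw), 0.002 * exp(0.5), tolerance = 1e-12)

  # querying before the first knot carries the first value backward, loudly
  late <- new_trajectory(100, 7)
  expect_warning(h <- hazard_at(10, late, 0, pr), "first")
  expect_equal(h, 0.01 * 2^7)
})

test_that("hazard parameter validation rejects bad baselines", {
  expect_error(hazard_params(0, 0, c(0, 500), c(0.001, 0)),
               class = "cmcflow_argument_error")
  expect_error(hazard_params(0, 0, c(100, 500), c(1e-4, 1e-4)),
               class = "cmcflow_argument_error")
  expect_error(new_trajectory(c(5, 5), c(1, 2)),
               class = "cmcflow_argument_error")
  expect_error(new_trajectory(c(0, 5), c(1, -2)),
               class = "cmcflow_argument_error")
})

test_that("event-time simulation matches the analytic survivor function", {
  # constant hazard, no covariates: exponential with mean 100 days
  pr <- hazard_params(0, 0, 0, 0.01)
  traj <- new_trajectory(0, 0)
  set.seed(10)
  draws <- replicate(1e4, simulate_event_time(traj, 0, pr, horizon = 1e6)$time)
  expect_lt(abs(mean(draws) - 100), 3 * sd(draws) / sqrt(1e4))

  # horizon 0 censors immediately
  z <- simulate_event_time(traj, 0, pr, horizon = 0)
  expect_false(z$event)
  expect_equal(z$time, 0)

  # piecewise hazard with a covariate step: compare the empirical survivor
  # function to exp(-H(t)) on a grid
  pr2 <- hazard_params(0.5, 0.1, c(0, 200), c(0.002, 0.004))
  traj2 <- new_trajectory(c(0, 300), c(1, 2))
  H <- function(t) {
    seg <- function(lo, hi, rate) max(0, min(t, hi) - lo) * rate
    seg(0, 200, 0.002 * exp(0.5 * 1 + 0.1)) +
      seg(200, 300, 0.004 * exp(0.5 * 1 + 0.1)) +
      seg(300, Inf, 0.004 * exp(0.5 * 2 + 0.1))
  }
  set.seed(11)
  tt <- replicate(1e4, simulate_event_time(traj2, 1, pr2, horizon = 1e5)$time)
  for (g in c(50, 150, 250, 350, 500, 800)) {
    s_emp <- mean(tt > g)
    s_true <- exp(-H(g))
    expect_lt(abs(s_emp - s_true), 3 * sqrt(s_true * (1 - s_true) / 1e4) + 1e-4)
  }

  # stochastic ordering: stronger covariate effect shifts events earlier
  set.seed(12)
  med_lo <- median(replicate(2000, simulate_event_time(
    new_trajectory(0, 1), 0, hazard_params(0.2, 0, 0, 0.001), 1e6)$time))
  med_hi <- median(replicate(2000, simulate_event_time(
    new_trajectory(0, 1), 0, hazard_params(1.0, 0, 0, 0.001), 1e6)$time))
  expect_lt(med_hi, med_lo)
})

test_that("synthetic cohorts are reproducible, valid, and feed the risk pipeline", {
  cfg <- synthetic_cohort_config(n_patients = 38, rng_seed = 5)
  co <- synthesize_cohort(cfg)
  expect_s3_class(co, "cmc_cohort")
  expect_equal(nrow(co$patients), 38)
  expect_identical(co$patients,
                   synthesize_cohort(cfg)$patients)  # seed-reproducible

  # the whole stratification pipeline runs downstream
  tab <- contingency(co, 2)
  expect_false(tab$untestable)
  expect_equal(tab$a + tab$b + tab$c + tab$d, 38L)
  p <- suppressWarnings(fisher_exact_two_tailed(tab))
  expect_true(p > 0 && p <= 1)

  # visit counts respect the configured range
  visits <- table(co$samples$patient_id)
  expect_true(all(visits >= 1 & visits <= 6))
})

test_that("a strong CMC effect concentrates metastases in the high-count group", {
  cfg <- synthetic_cohort_config(
    n_patients = 500,
    params = hazard_params(1.5, 0.3, c(0, 500), c(2e-5, 4e-5)),
    rng_seed = 21)
  co <- synthesize_cohort(cfg)
  g <- classify_by_threshold(co, 2)
  frac_high <- mean(g$high$metastasis)
  frac_low <- mean(g$low$metastasis)
  expect_gt(frac_high, frac_low)
})

test_that("with beta = alpha = 0 the Fisher p-value is null-calibrated", {
  null_params <- hazard_params(0, 0, c(0, 500), c(2e-4, 4e-4))
  set.seed(31)
  ps <- vapply(1:200, function(i) {
    co <- synthesize_cohort(synthetic_cohort_config(
      n_patients = 60, params = null_params, rng_seed = 30000 + i))
    tab <- contingency(co, 2)
    suppressWarnings(fisher_exact_two_tailed(tab))
  }, 0)
  # exact test is conservative/discrete: rejection rate must not exceed
  # nominal, and p-values must not pile up near zero
  expect_lte(mean(ps <= 0.05), 0.07)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("counting-process expansion carries the step covariate to each interval", {
  ser <- serial_cohort()
  cp <- build_counting_process(ser, transform = "identity")
  # P1: knots 0 and 200, event at 300 -> (0,200] x=0, (200,300] x=4, event
  p1 <- cp[cp$patient_id == "P1", ]
  expect_equal(p1$start, c(0, 200))
  expect_equal(p1$stop, c(200, 300))
  expect_equal(p1$x, c(0, 4))
  expect_equal(p1$event, c(FALSE, TRUE))
  # P5: one knot at 0, event at 90
  p5 <- cp[cp$patient_id == "P5", ]
  expect_equal(nrow(p5), 1)
  expect_equal(p5$x, 120)
  expect_true(p5$event)
  # log1p transform
  cpl <- build_counting_process(ser, transform = "log1p")
  expect_equal(cpl$x, log1p(cp$x))
  # stage encoding: I/II/III ordinal, mucosal as advanced
  expect_equal(stage_to_z(c("1A", "2C", "3B", "Mucosal")), c(1, 2, 3, 3))
  expect_true(is.na(stage_to_z("Unknown")))
})

test_that("the partial log-likelihood reduces correctly in symmetric and null cases", {
  # single event, two at-risk patients with equal covariates -> log(1/2)
  cp <- data.frame(patient_id = c("a", "b"), start = 0, stop = c(50, 80),
                   event = c(TRUE, FALSE), x = 1, z = 2)
  expect_equal(cox_partial_loglik(0.7, -0.2, cp), log(1 / 2),
               tolerance = 1e-12)

  # beta = alpha = 0: loglik is -sum over events of log(risk-set size)
  set.seed(40)
  co <- synthesize_cohort(synthetic_cohort_config(n_patients = 80,
                                                  rng_seed = 41))
  cpx <- build_counting_process(co)
  ev_times <- sort(cpx$stop[cpx$event])
  expected <- -sum(vapply(ev_times, function(t) {
    log(sum(cpx$start < t & t <= cpx$stop))
  }, 0))
  expect_equal(cox_partial_loglik(0, 0, cpx), expected, tolerance = 1e-10)

  expect_error(cox_partial_loglik(0, 0, cp[2, ]),
               class = "cmcflow_argument_error")
})

test_that("partial likelihood and fit agree with the reference implementation", {
  skip_if_not_installed("survival")
  co <- synthesize_cohort(synthetic_cohort_config(n_patients = 150,
                                                  rng_seed = 50))
  cp <- build_counting_process(co)
  ref <- survival::coxph(survival::Surv(start, stop, event) ~ x + z,
                         data = cp, ties = "breslow")
  # loglik agreement at the reference optimum
  expect_equal(cox_partial_loglik(coef(ref)[1], coef(ref)[2], cp),
               ref$loglik[2], tolerance = 1e-8)
  # and at arbitrary parameter values
  ref0 <- survival::coxph(survival::Surv(start, stop, event) ~ x + z,
                          data = cp, ties = "breslow",
                          init = c(0.3, -0.1), control =
                            survival::coxph.control(iter.max = 0))
  expect_equal(cox_partial_loglik(0.3, -0.1, cp), ref0$loglik[2],
               tolerance = 1e-8)
  # full fit: coefficients and standard errors
  f <- fit_cox(cp)
  expect_true(f$converged)
  expect_equal(unname(f$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("the partial likelihood is concave along evaluated points", {
  co <- synthesize_cohort(synthetic_cohort_config(n_patients = 100,
                                                  rng_seed = 60))
  cp <- build_counting_process(co)
  rs <- cmcflow:::cox_risk_structure(cp)
  set.seed(61)
  for (i in 1:20) {
    theta <- rnorm(2, 0, 1)
    info <- cmcflow:::cox_eval(theta, rs)$info
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-8))  # observed information PSD everywhere
  }
})

test_that("degenerate designs are flagged instead of crashing", {
  # constant covariates across everyone: non-identifiable
  cp <- data.frame(patient_id = letters[1:6], start = 0,
                   stop = c(10, 20, 30, 40, 50, 60),
                   event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                   x = 2, z = 3)
  f <- fit_cox(cp)
  expect_false(f$converged)
  expect_match(f$message, "non-identifiable")

  # complete separation: every event carried the larger covariate and
  # events precede all censorings -> monotone likelihood
  sep <- data.frame(patient_id = letters[1:6], start = 0,
                    stop = c(1, 2, 3, 50, 60, 70),
                    event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    x = c(5, 5, 5, 0, 0, 0), z = c(1, 2, 3, 1, 2, 3))
  fs <- fit_cox(sep)
  expect_false(fs$converged)

  expect_error(fit_cox(cp[c(1, 4), ]), class = "cmcflow_argument_error")
})

test_that("the fitter recovers parameters and its SEs are calibrated as n grows", {
  # moderate-n recovery: estimates near truth, within a few model SEs
  est <- t(vapply(1:6, function(s) {
    co <- synthesize_cohort(synthetic_cohort_config(n_patients = 400,
                                                    rng_seed = 600 + s))
    f <- fit_cox(co)
    c(f$coef, f$se)
  }, numeric(4)))
  expect_lt(abs(mean(est[, 1]) - 0.5), 3 * sd(est[, 1]) / sqrt(6) + 0.02)
  expect_lt(abs(mean(est[, 2]) - 0.3), 3 * sd(est[, 2]) / sqrt(6) + 0.05)
  # model SE approximates the sampling spread
  expect_lt(abs(mean(est[, 3]) / sd(est[, 1]) - 1), 0.8)
})
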