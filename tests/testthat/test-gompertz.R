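test_that("the MLE matches a brute-force grid oracle without truncation", {
  set.seed(71)
  n <- 2000
  b0 <- -8; g <- 0.08
  t_event <- sample_gompertz_age(rep(0, n), b0, g, 0, rexp(n))
  cens <- 90
  status <- as.integer(t_event <= cens)
  exit <- pmin(t_event, cens)
  fit <- fit_gompertz_ph(rep(0, n), exit, status)
  oracle <- oracle_gompertz_grid(rep(0, n), exit, status)
  expect_lt(abs(fit$b0[["all"]] - oracle[["b0"]]), 1e-4)
  expect_lt(abs(fit$gamma[["all"]] - oracle[["gamma"]]), 1e-4)
})

test_that("sex-specific slopes are recovered within 3 SE under truncation", {
  bp <- within(default_biomarker_params(), {
    theta_mort <- 0; theta_lre <- 0
  })
  sim <- simulate_cohort(sim_config(n = 20000, seed = 73, kappa = 0,
                                    sigma_a = 0, biomarker_params = bp))
  coh <- sim$cohort
  fit <- fit_gompertz_ph(coh$age, coh$age + coh$followup_time, coh$death,
                         sex = coh$sex)
  for (s in c("female", "male")) {
    expect_lt(abs(fit$gamma[[s]] - 0.09), 3 * fit$se_gamma[[s]])
    expect_lt(abs(fit$mrdt[[s]] - log(2) / 0.09), 1.5)
  }
  expect_lt(fit$gradient_norm, 1e-6 * (1 + abs(fit$loglik)))
})

test_that("a pure-noise covariate rarely moves the log-likelihood", {
  # twice the log-likelihood gain is asymptotically chi-square(1); the
  # 99.9% quantile should be exceeded only ~0.1% of the time
  exceed <- 0
  for (r in 1:20) {
    set.seed(700 + r)
    n <- 1500
    a0 <- runif(n, 50, 80)
    t_event <- sample_gompertz_age(a0, -9.5, 0.09, 0, rexp(n))
    exit <- pmin(t_event, a0 + 8)
    status <- as.integer(t_event <= a0 + 8)
    noise <- matrix(rnorm(n), dimnames = list(NULL, "noise"))
    f0 <- fit_gompertz_ph(a0, exit, status)
    f1 <- fit_gompertz_ph(a0, exit, status, x = noise)
    if (2 * (f1$loglik - f0$loglik) > qchisq(0.999, 1)) exceed <- exceed + 1
  }
  expect_lte(exceed, 1)
})

test_that("covariate effects are recovered jointly with the baseline", {
  set.seed(79)
  n <- 8000
  a0 <- runif(n, 50, 80)
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  beta <- c(0.4, -0.25)
  t_event <- sample_gompertz_age(a0, -9.5, 0.09, drop(x %*% beta), rexp(n))
  exit <- pmin(t_event, a0 + 10)
  status <- as.integer(t_event <= a0 + 10)
  fit <- fit_gompertz_ph(a0, exit, status, x = x)
  expect_lt(abs(fit$beta[["u"]] - 0.4), 3 * fit$se_beta[["u"]])
  expect_lt(abs(fit$beta[["v"]] + 0.25), 3 * fit$se_beta[["v"]])
  expect_lt(abs(fit$gamma[["all"]] - 0.09), 3 * fit$se_gamma[["all"]])
})

test_that("the fit agrees with an independent parametric survival fitter", {
  skip_if_not_installed("flexsurv")
  set.seed(83)
  n <- 3000
  t_event <- sample_gompertz_age(rep(0, n), -6, 0.07, 0, rexp(n))
  cens <- quantile(t_event, 0.8)
  exit <- pmin(t_event, cens)
  status <- as.integer(t_event <= cens)
  fit <- fit_gompertz_ph(rep(0, n), exit, status)
  fs <- flexsurv::flexsurvreg(survival::Surv(exit, status) ~ 1,
                              dist = "gompertz")
  expect_equal(fit$gamma[["all"]], fs$res["shape", "est"], tolerance = 1e-4)
  expect_equal(exp(fit$b0[["all"]]), fs$res["rate", "est"], tolerance = 1e-4)
})

test_that("too few deaths in a stratum refuses to fit", {
  set.seed(87)
  n <- 60
  a0 <- runif(n, 50, 70)
  exit <- a0 + 5
  status <- c(rep(1L, 12), rep(0L, n - 12))
  sex <- rep(c("female", "male"), each = 30)  # 12 deaths, all female
  expect_error(fit_gompertz_ph(a0, exit, status, sex = sex),
               "fewer than 10 deaths.*male")
})

test_that("mortality-rate doubling time follows ln(2)/gamma", {
  expect_equal(mrdt(log(2)), 1.0)
  expect_equal(round(mrdt(0.0866), 2), 8.00)
  expect_error(mrdt(0), "undefined")
  expect_error(mrdt(-0.05), "undefined")
  # doubling identity on a fitted-style object
  m <- fake_gompertz(-9, 0.085)
  h <- gompertz_hazard(m, c(65, 65 + mrdt(0.085)), NULL)
  expect_equal(h[2] / h[1], 2, tolerance = 1e-12)
})

test_that("fixing the slope from another model is honored", {
  set.seed(91)
  n <- 3000
  a0 <- runif(n, 50, 80)
  t_event <- sample_gompertz_age(a0, -9.5, 0.09, 0, rexp(n))
  exit <- pmin(t_event, a0 + 8)
  status <- as.integer(t_event <= a0 + 8)
  fit <- fit_gompertz_ph(a0, exit, status, gamma_fixed = c(all = 0.07))
  expect_equal(unname(fit$gamma[["all"]]), 0.07)
  expect_true(fit$gamma_fixed)
})
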