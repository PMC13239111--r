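test_that("agreement metrics follow their definitions", {
  x <- c(48, 61, 70, 82)
  expect_equal(agreement(x, x), list(r = 1, rmse = 0, mae = 0))
  a1 <- agreement(x + 1, x)
  expect_equal(a1$r, 1); expect_equal(a1$rmse, 1); expect_equal(a1$mae, 1)
  # constant reference: error metrics survive, correlation is undefined
  expect_warning(a2 <- agreement(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_equal(a2$rmse, sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(a2$mae, 2 / 3, tolerance = 1e-10)
  expect_true(is.na(a2$r))
  expect_error(agreement(1:2, 2:3), "at least 3")
  # r is invariant to positive affine maps; rmse/mae symmetric in arguments
  y <- x + rnorm(4)
  expect_equal(agreement(2 * x + 5, y)$r, agreement(x, y)$r)
  expect_equal(agreement(x, y)[c("rmse", "mae")],
               agreement(y, x)[c("rmse", "mae")])
})

test_that("AUROC equals the pairwise Mann-Whitney oracle, ties counted half", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auroc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(127)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    score <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # forces ties
    label <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(auroc(score, label)$auc,
                     oracle_auc_pairwise(score, label))
  }
  expect_error(auroc(1:5, rep(1, 5)), "both classes")
})

test_that("complementing a tie-free score complements the AUROC", {
  set.seed(131)
  score <- rnorm(60)
  label <- rbinom(60, 1, 0.4)
  expect_equal(auroc(score, label)$auc + auroc(-score, label)$auc, 1)
})

test_that("the paired DeLong test behaves at its boundaries and symmetries", {
  set.seed(137)
  score <- rnorm(80); label <- rbinom(80, 1, 0.5)
  same <- delong_test(score, score, label)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  other <- score + rnorm(80, sd = 2)
  ab <- delong_test(score, other, label)
  ba <- delong_test(other, score, label)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("DeLong variance agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(139)
  n <- 150
  label <- rbinom(n, 1, 0.4)
  s1 <- rnorm(n) + label
  s2 <- rnorm(n) + 0.5 * label
  mine <- delong_test(s1, s2, label)
  ref <- pROC::roc.test(pROC::roc(label, s1, quiet = TRUE),
                        pROC::roc(label, s2, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(unname(mine$z), unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  a <- auroc(s1, label)
  ref_ci <- pROC::ci.auc(pROC::roc(label, s1, quiet = TRUE), method = "delong")
  expect_equal(a$auc, as.numeric(pROC::auc(pROC::roc(label, s1, quiet = TRUE))))
  expect_equal(a$ci[1], ref_ci[1], tolerance = 1e-10)
  expect_equal(a$ci[2], ref_ci[3], tolerance = 1e-10)
})

test_that("Cox hazard ratios per SD honor weights and affine invariance", {
  set.seed(149)
  n <- 600
  x <- rnorm(n)
  time <- rexp(n, rate = 0.1 * exp(0.4 * x))
  event <- as.integer(time < 8); time <- pmin(time, 8)
  unw <- cox_hr_per_sd(time, event, x)
  w1 <- cox_hr_per_sd(time, event, x, weights = rep(1, n))
  expect_equal(unw$hr, w1$hr, tolerance = 1e-12)
  expect_equal(unw$ci, w1$ci, tolerance = 1e-12)
  # affine rescaling of the exposure leaves the per-SD HR unchanged
  resc <- cox_hr_per_sd(time, event, 3.7 * x - 12)
  expect_equal(resc$hr, unw$hr, tolerance = 1e-10)
  expect_true(unw$ci[1] <= unw$hr && unw$hr <= unw$ci[2])
  expect_error(cox_hr_per_sd(time, event, rep(1, n)), "constant")
  expect_error(cox_hr_per_sd(time[1:20], rep(0, 20), x[1:20]), "10 events")
})

test_that("log-rank matches an explicit risk-set oracle and its null", {
  # identical groups (duplicated data) separate nothing
  time <- c(1, 2, 3, 4, 5); event <- c(1, 0, 1, 1, 0)
  lr0 <- km_logrank(c(time, time), c(event, event),
                    rep(c("a", "b"), each = 5))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  # six-subject worked example against the hand risk-set computation
  t6 <- c(1, 3, 4, 2, 5, 6); e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- rep(c("decelerated", "accelerated"), each = 3)
  lr <- km_logrank(t6, e6, g6)
  orc <- oracle_logrank(t6, e6, g6)
  expect_equal(lr$chi2, orc$chi2, tolerance = 1e-10)
  expect_equal(lr$p, orc$p, tolerance = 1e-10)
  # random instances
  set.seed(151)
  for (i in 1:10) {
    n <- 40
    tt <- sample(1:15, n, replace = TRUE)
    ee <- rbinom(n, 1, 0.6)
    gg <- sample(c("x", "y"), n, replace = TRUE)
    if (sum(ee) == 0 || length(unique(gg)) < 2) next
    expect_equal(km_logrank(tt, ee, gg)$chi2,
                 oracle_logrank(tt, ee, gg)$chi2, tolerance = 1e-8)
  }
  expect_error(km_logrank(time, rep(0, 5), c("a", "a", "b", "b", "b")),
               "no events")
})

test_that("a doubled hazard is detected by the log-rank test", {
  detections <- 0
  for (r in 1:10) {
    set.seed(850 + r)
    n <- 1000
    grp <- rep(c("lo", "hi"), each = n / 2)
    rate <- ifelse(grp == "hi", 0.10, 0.05)
    tt <- rexp(n, rate)
    ee <- as.integer(tt < 10); tt <- pmin(tt, 10)
    if (km_logrank(tt, ee, grp)$p < 0.05) detections <- detections + 1
  }
  expect_gte(detections, 9)
})

test_that("the full evaluation battery emits a coherent report", {
  sim <- simulate_cohort(sim_config(n = 4000, seed = 157))
  model <- fit_lai(sim$cohort, nfolds = 5, seed = 7)
  rep_ <- evaluate_lai(model, sim$cohort)
  expect_s3_class(rep_, "lai_eval")
  expect_true(all(c("death", "lre") %in% names(rep_$outcomes)))
  for (oc in names(rep_$outcomes)) {
    o <- rep_$outcomes[[oc]]
    expect_true(o$auroc_lai$auc >= 0 && o$auroc_lai$auc <= 1)
    expect_true(o$auroc_lai$ci[1] <= o$auroc_lai$auc &&
                  o$auroc_lai$auc <= o$auroc_lai$ci[2])
    expect_true(o$hr_per_sd$ci[1] <= o$hr_per_sd$hr &&
                  o$hr_per_sd$hr <= o$hr_per_sd$ci[2])
  }
  expect_gte(rep_$agreement$rmse, rep_$agreement$mae)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$agreement$r, rep_$agreement$r, tolerance = 1e-12)
})
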