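test_that("standardization centers training data and is frozen thereafter", {
  sim <- small_sim(n = 500, seed = 31)
  spec <- lai_feature_spec("lai13")
  std <- standardize_features(sim$cohort, spec)
  expect_true(all(abs(colMeans(std$x)) < 1e-10))
  expect_true(all(abs(apply(std$x, 2, sd) - 1) < 1e-10))
  # apply stored params to a shifted cohort: shift must survive
  shifted <- sim$cohort
  shifted$alt <- shifted$alt + 10
  std2 <- standardize_features(shifted, spec, params = std$params)
  shift_sd <- 10 / std$params$sd[["alt"]]
  expect_equal(mean(std2$x[, "alt"]), shift_sd, tolerance = 1e-8)
})

test_that("zero-variance features are refused by name", {
  df <- make_cohort_df(20)
  df$death <- rep(c(0L, 1L), 10)
  cohort <- as_lai_cohort(df)  # biomarkers are constant in this fixture
  expect_error(standardize_features(cohort, lai_feature_spec("lai13")),
               "zero-variance.*bmi")
})

test_that("an overwhelming penalty zeroes every coefficient", {
  sim <- small_sim(n = 400, seed = 37)
  spec <- lai_feature_spec("lai13")
  std <- standardize_features(sim$cohort, spec)
  fit <- fit_elastic_net_cox(std$x, sim$cohort$lre_time, sim$cohort$lre,
                             alpha = 0.5, lambda = 1e6)
  expect_true(all(fit$beta == 0))
})

test_that("the unpenalized solution matches a Newton partial-likelihood oracle", {
  set.seed(41)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta_true <- c(0.5, -0.3, 0.2)
  time <- rexp(n, rate = 0.2 * exp(drop(x %*% beta_true)))
  c0 <- quantile(time, 0.7)
  event <- as.integer(time < c0)  # continuous times: tie-free among events
  time <- pmin(time, c0)
  fit <- fit_elastic_net_cox(x, time, event, alpha = 0.5, lambda = 0)
  oracle <- oracle_cox_newton(x, time, event)
  expect_lt(max(abs(fit$beta - oracle)), 1e-3)
})

test_that("the L1 norm is nondecreasing along a decreasing penalty path", {
  sim <- small_sim(n = 600, seed = 43)
  spec <- lai_feature_spec("lai5")
  std <- standardize_features(sim$cohort, spec)
  fit <- fit_elastic_net_cox(std$x, sim$cohort$lre_time, sim$cohort$lre,
                             alpha = 0.5, nfolds = 5, seed = 1)
  l1 <- colSums(abs(fit$beta_path))
  expect_true(all(diff(l1) > -1e-8))
})

test_that("lasso sparsifies under strong penalty while ridge never does", {
  sim <- small_sim(n = 800, seed = 47)
  spec <- lai_feature_spec("lai13")
  std <- standardize_features(sim$cohort, spec)
  y <- list(t = sim$cohort$lre_time, e = sim$cohort$lre)
  lasso <- fit_elastic_net_cox(std$x, y$t, y$e, alpha = 1, nfolds = 5, seed = 2)
  ridge <- fit_elastic_net_cox(std$x, y$t, y$e, alpha = 0, nfolds = 5, seed = 2)
  mid <- ceiling(ncol(lasso$beta_path) / 3)  # early path = strong penalty
  expect_gt(sum(lasso$beta_path[, mid] == 0), 0)
  expect_true(all(ridge$beta_path[, ncol(ridge$beta_path)] != 0))
})

test_that("cross-validated penalty choice is reproducible under a seed", {
  sim <- small_sim(n = 600, seed = 53)
  spec <- lai_feature_spec("lai5")
  std <- standardize_features(sim$cohort, spec)
  f1 <- fit_elastic_net_cox(std$x, sim$cohort$lre_time, sim$cohort$lre,
                            nfolds = 5, seed = 9)
  f2 <- fit_elastic_net_cox(std$x, sim$cohort$lre_time, sim$cohort$lre,
                            nfolds = 5, seed = 9)
  expect_identical(f1$lambda_selected, f2$lambda_selected)
  expect_identical(f1$beta, f2$beta)
})

test_that("per-category fitting yields the documented sub-model sizes", {
  sim <- small_sim(n = 2000, seed = 59)
  rs13 <- fit_risk_scores(sim$cohort, lai_feature_spec("lai13"),
                          nfolds = 5, seed = 1)
  expect_named(rs13$models, c("clinical", "metabolic", "enzyme", "imaging"))
  expect_equal(unname(sapply(rs13$models, function(m) length(m$beta))),
               c(3L, 5L, 3L, 2L))
  rs5 <- fit_risk_scores(sim$cohort, lai_feature_spec("lai5"),
                         nfolds = 5, seed = 1)
  expect_equal(sum(sapply(rs5$models, function(m) length(m$beta))), 5L)
})

test_that("training scores are centered and linear in the features", {
  sim <- small_sim(n = 2000, seed = 61)
  rs <- fit_risk_scores(sim$cohort, lai_feature_spec("lai13"),
                        nfolds = 5, seed = 1)
  s <- compute_risk_scores(rs, sim$cohort)
  expect_true(all(abs(colMeans(s)) < 1e-10))
  # linearity: score(x + delta) - score(x) = beta' (delta / sd)
  shifted <- sim$cohort
  shifted$ggt <- shifted$ggt + 7
  s2 <- compute_risk_scores(rs, shifted)
  expected_shift <- rs$models$enzyme$beta[["ggt"]] * 7 /
    rs$standardization$sd[["ggt"]]
  expect_equal(unname(s2[, "enzyme"] - s[, "enzyme"]),
               rep(expected_shift, nrow(s)), tolerance = 1e-10)
  expect_equal(s2[, "imaging"], s[, "imaging"], tolerance = 1e-12)
})

test_that("score arithmetic follows s = beta' z - m", {
  rs <- structure(list(
    models = list(toy = list(markers = c("fap", "lsm"),
                             beta = c(fap = 0.5, lsm = -0.2),
                             lambda = 0.1, m = 0)),
    standardization = list(mean = c(fap = 248.9, lsm = 7.4),
                           sd = c(fap = 34.7, lsm = 2.6)),
    alpha = 0.5, nfolds = 10L, seed = 1L,
    spec = lai_feature_spec("lai13", biomarkers = c("fap", "lsm"),
                            grouping = c(fap = "toy", lsm = "toy"))),
    class = "lai_risk_scores")
  cohort <- data.frame(fap = 248.9 + 1 * 34.7, lsm = 7.4 + 2 * 2.6)
  s <- compute_risk_scores(rs, cohort)
  expect_equal(unname(s[1, "toy"]), 0.5 * 1 + (-0.2) * 2)
})

test_that("a marker driving LRE makes its category's score the strongest", {
  bp <- default_biomarker_params()
  bp$theta_lre <- ifelse(bp$marker == "lsm", 1.0, 0)
  sim <- simulate_cohort(sim_config(n = 8000, seed = 67,
                                    biomarker_params = bp))
  rs <- fit_risk_scores(sim$cohort, lai_feature_spec("lai13"),
                        nfolds = 5, seed = 1)
  s <- compute_risk_scores(rs, sim$cohort)
  assoc <- apply(s, 2, function(v) {
    if (sd(v) == 0) return(0)
    abs(coef(survival::coxph(
      survival::Surv(sim$cohort$lre_time, sim$cohort$lre) ~ scale(v))))
  })
  expect_equal(names(which.max(assoc)), "imaging")
})
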