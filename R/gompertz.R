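#' Fit a left-truncated Gompertz proportional-hazards mortality model
#'
#' Maximum likelihood on the age timescale: each subject enters observation
#' at `entry_age` (left truncation) and exits at `exit_age` by death
#' (`status = 1`) or censoring. The hazard for subject i in baseline stratum
#' s is `h_i(u) = exp(b0_s + gamma_s * u + beta' x_i)`, so the log-likelihood
#' is `sum_i d_i (b0_s + gamma_s a1_i + beta' x_i) - (H_i(a1_i) - H_i(a0_i))`
#' with the closed-form Gompertz cumulative hazard (see
#' [gompertz_interval_survival()]).
#'
#' Optimization is quasi-Newton (BFGS) on `(b0_s, log gamma_s, beta)` with
#' the analytic gradient; `gamma > 0` by construction. Initialization uses
#' the closed-form `b0` of an exponential-in-age fit at `gamma = 0.05`.
#'
#' @param entry_age age at entry (years).
#' @param exit_age age at exit; `entry_age + followup_time`.
#' @param status 0/1 death indicator.
#' @param sex optional per-subject stratum labels for sex-specific baselines
#'   `(b0_s, gamma_s)`; `NULL` fits a single shared baseline.
#' @param x optional covariate matrix (e.g. risk scores) with coefficients
#'   shared across strata; `NULL` for the null (age + sex) model.
#' @param gamma_fixed optional named per-stratum slope; when given, `gamma`
#'   is held fixed and only `b0` (and `beta`) are estimated.
#' @param grad_tol convergence tolerance on the gradient max-norm.
#' @param max_iter BFGS iteration cap.
#' @return Object of class `gompertz_ph`: per-stratum `b0`, `gamma`, `mrdt`
#'   (`NA` with a warning flag when the slope collapses to the boundary),
#'   shared `beta`, `loglik`, `se` (from the observed information; delta
#'   method for `gamma`), and convergence diagnostics.
#' @export
fit_gompertz_ph <- function(entry_age, exit_age, status, sex = NULL, x = NULL,
                            gamma_fixed = NULL, grad_tol = 1e-8,
                            max_iter = 500L) {
  n <- length(entry_age)
  stopifnot(length(exit_age) == n, length(status) == n,
            all(exit_age >= entry_age), all(status %in% c(0, 1)))
  strata <- if (is.null(sex)) factor(rep("all", n)) else factor(sex)
  slev <- levels(strata)
  S <- length(slev)
  sidx <- as.integer(strata)
  for (s in seq_len(S)) {
    d_s <- sum(status[sidx == s])
    if (d_s < 10) {
      stop("fewer than 10 deaths in stratum '", slev[s],
           "' (", d_s, "); Gompertz fit refused", call. = FALSE)
    }
  }
  if (!is.null(x)) {
    x <- as.matrix(x)
    stopifnot(nrow(x) == n)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  p <- if (is.null(x)) 0L else ncol(x)
  fixed_gamma <- !is.null(gamma_fixed)
  if (fixed_gamma) {
    gamma_fixed <- if (S == 1L && length(gamma_fixed) == 1L) {
      stats::setNames(unname(gamma_fixed), slev)
    } else gamma_fixed[slev]
    stopifnot(all(gamma_fixed > 0), !anyNA(gamma_fixed))
  }

  # parameter layout: b0[1..S], (loggamma[1..S] unless fixed), beta[1..p]
  ib0 <- seq_len(S)
  ilg <- if (fixed_gamma) integer(0) else S + seq_len(S)
  ibeta <- if (p) S + length(ilg) + seq_len(p) else integer(0)

  unpack <- function(par) {
    gam <- if (fixed_gamma) unname(gamma_fixed) else exp(par[ilg])
    list(b0 = par[ib0], gamma = gam,
         beta = if (p) par[ibeta] else numeric(0))
  }

  negloglik <- function(par) {
    q <- unpack(par)
    eta <- if (p) drop(x %*% q$beta) else 0
    b0i <- q$b0[sidx]; gi <- q$gamma[sidx]
    H <- exp(b0i + eta + gi * entry_age) *
      expm1(gi * (exit_age - entry_age)) / gi
    ll <- sum(status * (b0i + gi * exit_age + eta)) - sum(H)
    -ll
  }
  neggrad <- function(par) {
    q <- unpack(par)
    eta <- if (p) drop(x %*% q$beta) else 0
    b0i <- q$b0[sidx]; gi <- q$gamma[sidx]
    e1 <- exp(gi * exit_age); e0 <- exp(gi * entry_age)
    w <- exp(b0i + eta)
    H <- w * (e1 - e0) / gi
    dH_dg <- w * ((exit_age * e1 - entry_age * e0) * gi - (e1 - e0)) / gi^2
    g <- numeric(length(par))
    for (s in seq_len(S)) {
      m <- sidx == s
      g[ib0[s]] <- sum(status[m]) - sum(H[m])
      if (!fixed_gamma) {
        g[ilg[s]] <- (sum(status[m] * exit_age[m]) - sum(dH_dg[m])) * q$gamma[s]
      }
    }
    if (p) {
      g[ibeta] <- drop(crossprod(x, status - H))
    }
    -g
  }

  # init: gamma = 0.05, closed-form b0 per stratum, beta = 0
  g0 <- if (fixed_gamma) unname(gamma_fixed) else rep(0.05, S)
  b0_init <- numeric(S)
  for (s in seq_len(S)) {
    m <- sidx == s
    denom <- sum(exp(g0[s] * entry_age[m]) *
                   expm1(g0[s] * (exit_age[m] - entry_age[m]))) / g0[s]
    b0_init[s] <- log(sum(status[m]) / denom)
  }
  par0 <- c(b0_init, if (!fixed_gamma) log(g0), rep(0, p))

  opt <- stats::optim(par0, negloglik, neggrad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  # Newton polish with the observed information: drives the gradient to
  # numerical zero, which BFGS alone does not guarantee at scale
  par <- opt$par
  f <- negloglik(par)
  tol_abs <- grad_tol * (1 + abs(f))
  newton_it <- 0L
  repeat {
    g <- neggrad(par)
    if (max(abs(g)) <= tol_abs || newton_it >= 30L) break
    H <- stats::optimHess(par, negloglik, neggrad)
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    if (all(step == 0)) break
    t_ls <- 1
    repeat {
      par_new <- par - t_ls * step
      f_new <- negloglik(par_new)
      if (is.finite(f_new) && f_new <= f + 1e-12 * abs(f)) break
      t_ls <- t_ls / 2
      if (t_ls < 1e-8) break
    }
    if (t_ls < 1e-8) break
    par <- par_new; f <- f_new
    newton_it <- newton_it + 1L
  }
  gnorm <- max(abs(neggrad(par)))
  if (!is.finite(f) || gnorm > tol_abs) {
    stop(sprintf(paste0("Gompertz fit did not converge: gradient max-norm ",
                        "%.3g (tolerance %.3g) after %d BFGS + %d Newton ",
                        "iterations (loglik %.6g)"),
                 gnorm, tol_abs, opt$counts[1], newton_it, -f),
         call. = FALSE)
  }
  opt$par <- par
  opt$value <- f
  opt$counts[1] <- opt$counts[1] + newton_it
  q <- unpack(opt$par)
  boundary <- !fixed_gamma & (log(q$gamma) < -13)
  if (any(boundary)) {
    warning("gamma collapsed to the boundary in stratum ",
            paste(slev[boundary], collapse = ", "),
            "; no aging signal, MRDT undefined", call. = FALSE)
  }

  hess <- stats::optimHess(opt$par, negloglik, neggrad)
  vcov <- tryCatch(solve(hess), error = function(e) {
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  se <- sqrt(pmax(diag(vcov), 0))
  se_gamma <- if (fixed_gamma) rep(NA_real_, S) else se[ilg] * q$gamma

  structure(list(
    strata = slev,
    b0 = stats::setNames(q$b0, slev),
    gamma = stats::setNames(q$gamma, slev),
    mrdt = stats::setNames(ifelse(boundary, NA_real_, log(2) / q$gamma), slev),
    beta = if (p) stats::setNames(q$beta, colnames(x)) else numeric(0),
    se_b0 = stats::setNames(se[ib0], slev),
    se_gamma = stats::setNames(se_gamma, slev),
    se_beta = if (p) stats::setNames(se[ibeta], colnames(x)) else numeric(0),
    gamma_fixed = fixed_gamma,
    boundary = stats::setNames(boundary, slev),
    loglik = -opt$value,
    gradient_norm = gnorm,
    iterations = unname(opt$counts[1]),
    n = n,
    events = sum(status)
  ), class = "gompertz_ph")
}

#' @export
print.gompertz_ph <- function(x, ...) {
  cat("Gompertz proportional-hazards mortality model (left-truncated, age timescale)\n")
  cat("  n =", x$n, " deaths =", x$events,
      " loglik =", format(x$loglik, digits = 8), "\n")
  for (s in x$strata) {
    cat(sprintf("  %-8s b0 = %8.4f (SE %.4f)  gamma = %.5f (SE %s)  MRDT = %s yr\n",
                s, x$b0[s], x$se_b0[s], x$gamma[s],
                ifelse(is.na(x$se_gamma[s]), "-",
                       sprintf("%.5f", x$se_gamma[s])),
                ifelse(is.na(x$mrdt[s]), "undefined",
                       sprintf("%.2f", x$mrdt[s]))))
  }
  if (length(x$beta)) {
    cat("  covariates:",
        paste(sprintf("%s=%.4f", names(x$beta), x$beta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mortality-rate doubling time
#'
#' `MRDT = ln(2) / gamma` years: the time for the age-specific hazard to
#' double under a Gompertz baseline, so `h(u + mrdt(gamma)) = 2 h(u)`.
#'
#' @param gamma per-year log-hazard slope, must be positive.
#' @return years.
#' @export
mrdt <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop("MRDT is undefined for gamma <= 0", call. = FALSE)
  }
  log(2) / gamma
}

#' Evaluate the model hazard at given ages
#'
#' @param model a `gompertz_ph` fit.
#' @param age ages (years).
#' @param sex stratum labels (ignored for single-stratum fits).
#' @param x covariate matrix matching the model's `beta` (or `NULL`).
#' @return hazard per year.
#' @export
gompertz_hazard <- function(model, age, sex = NULL, x = NULL) {
  stopifnot(inherits(model, "gompertz_ph"))
  s <- resolve_strata(model, sex, length(age))
  eta <- 0
  if (length(model$beta)) {
    stopifnot(!is.null(x))
    x <- as.matrix(x)
    eta <- drop(x[, names(model$beta), drop = FALSE] %*% model$beta)
  }
  unname(exp(model$b0[s] + model$gamma[s] * age + eta))
}

resolve_strata <- function(model, sex, n) {
  if (length(model$strata) == 1L) return(rep(model$strata, n))
  s <- as.character(sex)
  bad <- !s %in% model$strata
  if (any(bad)) {
    stop("no fitted stratum for sex value(s): ",
         paste(unique(s[bad]), collapse = ", "), call. = FALSE)
  }
  s
}

#' Liver aging acceleration from paired Gompertz models
#'
#' Converts the mortality-hazard ratio between the biomarker-informed
#' (full) and age-only (null) models into equivalent years:
#' `LAA = MRDT_s * log2(h_full(age) / h_null(age))`, both hazards evaluated
#' at the subject's own chronological age and the doubling time taken from
#' the null model (it defines the population mortality clock). Positive LAA
#' means accelerated liver aging; negative means delayed. LAA is invariant
#' to any common rescaling of the two models' baseline hazards.
#'
#' @param null_model `gompertz_ph` fit with no covariates (CA + sex).
#' @param full_model `gompertz_ph` fit with the risk-score covariates.
#' @param age chronological ages.
#' @param sex sex labels (ignored for single-stratum models).
#' @param scores risk-score matrix for the full model's covariates.
#' @return LAA in years.
#' @export
compute_laa <- function(null_model, full_model, age, sex = NULL,
                        scores = NULL) {
  s <- resolve_strata(null_model, sex, length(age))
  m <- null_model$mrdt[s]
  if (anyNA(m)) {
    stop("MRDT undefined in the null model; cannot compute LAA",
         call. = FALSE)
  }
  h_null <- gompertz_hazard(null_model, age, sex)
  h_full <- gompertz_hazard(full_model, age, sex, scores)
  unname(m * log2(h_full / h_null))
}

#' Liver Aging Index
#'
#' Biological age of the liver in years: chronological age plus liver aging
#' acceleration, so `lai - age == laa` exactly.
#'
#' @param age chronological age (years).
#' @param laa liver aging acceleration (years).
#' @return years.
#' @export
compute_lai <- function(age, laa) age + laa

#' Training-quartile thresholds and acceleration classes
#'
#' `laa_quartiles()` returns the first and third quartiles of the training
#' LAA distribution (linear-interpolation quantiles, the `type = 7`
#' convention; class boundaries depend on this choice, which is fixed here).
#' `classify_laa()` assigns `accelerated` strictly above Q3, `decelerated`
#' strictly below Q1, and `intermediate` otherwise — values exactly at a
#' threshold are intermediate. Validation cohorts must be classified with
#' the training thresholds, never their own.
#'
#' @param laa_train training-cohort LAA values (n >= 4).
#' @return named numeric `c(q1, q3)`.
#' @export
laa_quartiles <- function(laa_train) {
  stopifnot(length(laa_train) >= 4, !anyNA(laa_train))
  q <- stats::quantile(laa_train, c(0.25, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' @rdname laa_quartiles
#' @param laa LAA values to classify.
#' @param thresholds output of [laa_quartiles()] (from the training cohort).
#' @return factor with levels decelerated < intermediate < accelerated.
#' @export
classify_laa <- function(laa, thresholds) {
  stopifnot(all(c("q1", "q3") %in% names(thresholds)),
            thresholds["q1"] <= thresholds["q3"])
  cls <- ifelse(laa > thresholds["q3"], "accelerated",
                ifelse(laa < thresholds["q1"], "decelerated", "intermediate"))
  factor(cls, levels = c("decelerated", "intermediate", "accelerated"))
}
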