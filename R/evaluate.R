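#' Agreement between a biological age and chronological age
#'
#' Pearson correlation, root mean square error, and mean absolute error
#' between two age vectors.
#'
#' @param lai predicted/biological ages (years).
#' @param ca chronological ages (years).
#' @return list with `r`, `rmse`, `mae`. When either vector is constant the
#'   correlation is undefined: `r` is `NA` with a warning (the error metrics
#'   are still returned).
#' @export
agreement <- function(lai, ca) {
  stopifnot(length(lai) == length(ca))
  if (length(lai) < 3) stop("need at least 3 pairs", call. = FALSE)
  r <- if (stats::sd(lai) == 0 || stats::sd(ca) == 0) {
    warning("correlation undefined for a constant vector", call. = FALSE)
    NA_real_
  } else {
    stats::cor(lai, ca)
  }
  d <- lai - ca
  list(r = r, rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
}

# DeLong structural components: for cases V10_i = P-hat(score beats a random
# control | case i), for controls V01_j analogously; AUC = mean(V10) =
# mean(V01), ties counted 1/2. Computed in O(n log n) via sorted lookups.
delong_components <- function(score, label) {
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  cases <- score[label == 1L]
  controls <- score[label == 0L]
  m <- length(cases); k <- length(controls)
  if (m == 0L || k == 0L) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  sc <- sort(controls); sk <- sort(cases)
  n_leq <- findInterval(cases, sc)
  n_lt <- findInterval(cases, sc, left.open = TRUE)
  v10 <- (n_lt + 0.5 * (n_leq - n_lt)) / k
  c_leq <- findInterval(controls, sk)
  c_lt <- findInterval(controls, sk, left.open = TRUE)
  v01 <- ((m - c_leq) + 0.5 * (c_leq - c_lt)) / m
  # AUC from the integer pair counts so it is exact, not a mean of ratios
  auc <- sum(n_lt + 0.5 * (n_leq - n_lt)) / (m * k)
  list(v10 = v10, v01 = v01, auc = auc, m = m, k = k)
}

#' AUROC with DeLong variance
#'
#' Mann-Whitney estimator of the area under the ROC curve (ties counted
#' one-half) with its variance from DeLong's structural components, and a
#' Wald 95% confidence interval clamped to `[0, 1]`.
#'
#' @param score numeric predictor.
#' @param label 0/1 outcome.
#' @return list with `auc`, `var`, `se`, `ci` (length 2), `n_cases`,
#'   `n_controls`.
#' @export
auroc <- function(score, label) {
  d <- delong_components(score, label)
  v <- stats::var(d$v10) / d$m + stats::var(d$v01) / d$k
  se <- sqrt(v)
  ci <- pmin(pmax(d$auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  list(auc = d$auc, var = v, se = se, ci = ci,
       n_cases = d$m, n_controls = d$k)
}

#' DeLong test for two correlated AUROCs
#'
#' Paired comparison of two scores measured on the same subjects against the
#' same 0/1 outcome, using the covariance of the DeLong structural
#' components; two-sided p from the normal reference. When both the AUC
#' difference and its estimated variance are zero (e.g. identical scores),
#' p = 1 by convention.
#'
#' @param score_a,score_b the two predictors (same subjects, same order).
#' @param label 0/1 outcome.
#' @return list with `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
delong_test <- function(score_a, score_b, label) {
  stopifnot(length(score_a) == length(score_b),
            length(score_a) == length(label))
  a <- delong_components(score_a, label)
  b <- delong_components(score_b, label)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$k
  delta <- a$auc - b$auc
  if (v_delta <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(v_delta)
  }
  p <- if (delta == 0 && v_delta <= 0) 1 else 2 * stats::pnorm(-abs(z))
  list(auc_a = a$auc, auc_b = b$auc, delta = delta,
       se = sqrt(max(v_delta, 0)), z = z, p = p)
}

#' Cox hazard ratio per 1 SD of an exposure
#'
#' Semiparametric Cox proportional-hazards association of a continuous
#' exposure (e.g. LAA) with a survival outcome, with the exposure
#' standardized to unit SD in the analysis cohort, optional adjustment
#' covariates, optional per-subject weights, Efron tie handling, and a Wald
#' 95% confidence interval. The result is invariant to affine rescaling of
#' the exposure.
#'
#' @param time follow-up times.
#' @param event 0/1 indicator.
#' @param exposure continuous exposure; standardized internally.
#' @param covariates optional data.frame of adjustment covariates.
#' @param weights optional positive per-subject weights.
#' @return list with `hr`, `ci` (length 2), `loghr`, `se`, `p`, `n`,
#'   `events`.
#' @export
cox_hr_per_sd <- function(time, event, exposure, covariates = NULL,
                          weights = NULL) {
  if (sum(event) < 10) stop("need at least 10 events", call. = FALSE)
  s <- stats::sd(exposure)
  if (s == 0) stop("exposure is constant", call. = FALSE)
  df <- data.frame(.time = time, .event = event, .exp = exposure / s)
  rhs <- ".exp"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    rhs <- paste(c(".exp", names(covariates)), collapse = " + ")
  }
  df$.w <- if (is.null(weights)) 1 else weights
  fit <- tryCatch(
    survival::coxph(stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
                    data = df, weights = .w, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        stop("Cox model failed to converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(
        survival::coxph(stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
                        data = df, weights = .w, ties = "efron"))
    })
  b <- stats::coef(fit)[".exp"]
  se <- sqrt(diag(fit$var))[which(names(stats::coef(fit)) == ".exp")]
  zq <- stats::qnorm(0.975)
  list(hr = unname(exp(b)),
       ci = unname(exp(b + c(-1, 1) * zq * se)),
       loghr = unname(b), se = unname(se),
       p = unname(2 * stats::pnorm(-abs(b / se))),
       n = fit$n, events = fit$nevent)
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' @param time follow-up times.
#' @param event 0/1 indicator.
#' @param group two-level grouping factor (e.g. decelerated vs accelerated).
#' @return list with `chi2`, `df`, `p`, and `curves` (data.frame of the KM
#'   estimates per group: `group`, `time`, `n_risk`, `n_event`, `surv`).
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least two nonempty groups",
                               call. = FALSE)
  if (sum(event) == 0) stop("no events; log-rank undefined", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_$n) - 1
  p <- stats::pchisq(sd_$chisq, df, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  grp <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  list(chi2 = unname(sd_$chisq), df = df, p = p, curves = curves)
}

#' Run the full validation battery for a fitted Liver Aging Index
#'
#' Applies the model to a cohort and computes: LAI-vs-CA agreement
#' (Pearson r, RMSE, MAE); discrimination of each requested outcome by LAI
#' and by CA (AUROC over cumulative event status with DeLong confidence
#' intervals and the paired DeLong comparison); the Cox hazard ratio per
#' 1 SD of LAA adjusted for age and sex (plus region, education, and
#' marital status when present), using the cohort's survey weights; and the
#' Kaplan-Meier log-rank separation between the accelerated (LAA > Q3) and
#' decelerated (LAA < Q1) classes under the training thresholds.
#'
#' @param model a `lai_model`.
#' @param cohort a `lai_cohort`.
#' @param outcomes subset of `c("death", "lre", "lrm")`.
#' @return Object of class `lai_eval`.
#' @export
evaluate_lai <- function(model, cohort, outcomes = c("death", "lre", "lrm")) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  pred <- predict(model, cohort)
  agr <- agreement(pred$lai, pred$age)

  outcome_time <- function(oc) switch(oc,
    death = cohort$followup_time, lre = cohort$lre_time,
    lrm = cohort$lrm_time)
  adj <- data.frame(age = cohort$age,
                    sex = factor(cohort$sex))
  for (extra in c("region", "education", "marital_status")) {
    if (extra %in% names(cohort) && length(unique(cohort[[extra]])) > 1) {
      adj[[extra]] <- factor(cohort[[extra]])
    }
  }
  w <- if ("weight" %in% names(cohort)) cohort$weight else NULL

  per_outcome <- list()
  for (oc in outcomes) {
    ev <- cohort[[oc]]
    if (sum(ev) < 10 || length(unique(ev)) < 2) next
    a_lai <- auroc(pred$lai, ev)
    a_ca <- auroc(pred$age, ev)
    dl <- delong_test(pred$lai, pred$age, ev)
    hr <- cox_hr_per_sd(outcome_time(oc), ev, pred$laa,
                        covariates = adj, weights = w)
    ext <- pred$class != "intermediate"
    lr <- km_logrank(outcome_time(oc)[ext], ev[ext],
                     droplevels(pred$class[ext]))
    per_outcome[[oc]] <- list(
      n = length(ev), events = sum(ev),
      auroc_lai = a_lai, auroc_ca = a_ca, delong = dl,
      hr_per_sd = hr,
      logrank = lr[c("chi2", "df", "p")]
    )
  }
  structure(list(agreement = agr, outcomes = per_outcome,
                 n = nrow(cohort),
                 class_counts = table(pred$class)),
            class = "lai_eval")
}

#' @export
print.lai_eval <- function(x, ...) {
  cat("Liver Aging Index evaluation (n =", x$n, ")\n")
  cat(sprintf("  agreement with CA: r = %.3f, RMSE = %.2f yr, MAE = %.2f yr\n",
              x$agreement$r, x$agreement$rmse, x$agreement$mae))
  for (oc in names(x$outcomes)) {
    o <- x$outcomes[[oc]]
    cat(sprintf(paste0("  %-5s (%d events): AUROC LAI %.3f [%.3f, %.3f] vs ",
                       "CA %.3f (DeLong p = %.3g); HR/SD %.2f [%.2f, %.2f]; ",
                       "log-rank chi2 = %.1f (p = %.3g)\n"),
                oc, o$events, o$auroc_lai$auc, o$auroc_lai$ci[1],
                o$auroc_lai$ci[2], o$auroc_ca$auc, o$delong$p,
                o$hr_per_sd$hr, o$hr_per_sd$ci[1], o$hr_per_sd$ci[2],
                o$logrank$chi2, o$logrank$p))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report a `lai_eval`.
#' @param path output path.
#' @param provenance optional named list stored under `provenance`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, provenance = NULL) {
  stopifnot(inherits(report, "lai_eval"))
  obj <- unclass(report)
  obj$class_counts <- as.list(obj$class_counts)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
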