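#' Build and standardize the active feature matrix
#'
#' Applies declared transforms (log where requested) and z-standardization.
#' When `params` is `NULL` the standardization means/SDs are estimated from
#' the data (a training call) and returned; otherwise the stored parameters
#' are reused unchanged (an apply call never re-estimates on new data).
#'
#' @param cohort a `lai_cohort` (or data.frame with the active biomarkers).
#' @param spec a [lai_feature_spec()].
#' @param params optional list with numeric vectors `mean` and `sd` from a
#'   previous training call.
#' @return list with `x` (n x p standardized matrix, columns in spec order)
#'   and `params`.
#' @export
standardize_features <- function(cohort, spec, params = NULL) {
  miss <- setdiff(spec$biomarkers, names(cohort))
  if (length(miss)) {
    stop("cohort lacks active feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(as.data.frame(cohort)[, spec$biomarkers, drop = FALSE])
  for (j in spec$biomarkers) {
    if (spec$transforms[[j]] == "log") {
      if (any(x[, j] <= 0)) {
        stop("log transform requires strictly positive values: ", j,
             call. = FALSE)
      }
      x[, j] <- log(x[, j])
    }
  }
  if (is.null(params)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    zero <- sdv <= 0 | !is.finite(sdv)
    if (any(zero)) {
      stop("zero-variance feature(s): ",
           paste(spec$biomarkers[zero], collapse = ", "), call. = FALSE)
    }
    params <- list(mean = mu, sd = sdv)
  }
  z <- sweep(sweep(x, 2, params$mean[colnames(x)]), 2,
             params$sd[colnames(x)], "/")
  list(x = z, params = params)
}

# Seeded, event-balanced fold assignment: events and censored subjects are
# each spread evenly across folds so no fold is left without events.
make_foldid <- function(event, nfolds, seed) {
  n <- length(event)
  if (sum(event) < nfolds) {
    stop("fewer events (", sum(event), ") than folds (", nfolds,
         "); cross-validation is degenerate", call. = FALSE)
  }
  foldid <- integer(n)
  set.seed(seed)
  for (grp in list(which(event == 1), which(event == 0))) {
    if (length(grp)) {
      foldid[grp] <- sample(rep_len(seq_len(nfolds), length(grp)))
    }
  }
  foldid
}

#' Fit an elastic-net Cox model with cross-validated penalty
#'
#' Maximizes the penalized Cox partial log-likelihood
#' `l(beta) - lambda * (alpha * ||beta||_1 + (1 - alpha) * ||beta||_2^2 / 2)`
#' along a decreasing penalty path, selecting the penalty that maximizes the
#' mean cross-validated partial likelihood (equivalently, minimizes CV
#' partial-likelihood deviance). Fold assignment is seeded and
#' event-balanced. Columns are assumed pre-standardized (see
#' [standardize_features()]).
#'
#' @param x standardized feature matrix (no intercept).
#' @param time event/censoring times (> 0).
#' @param event 0/1 indicator.
#' @param alpha elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda optional decreasing penalty path; a path ending in 0 gives
#'   the unpenalized partial-likelihood MLE at `lambda = 0`. A single value
#'   skips cross-validation.
#' @param nfolds number of CV folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @return list with `beta` (coefficients at the selected penalty),
#'   `lambda_selected`, `lambda` (path), `beta_path` (p x nlambda matrix),
#'   `cvm` (CV deviance per path value, `NULL` without CV), and `alpha`.
#' @export
fit_elastic_net_cox <- function(x, time, event, alpha = 0.5, lambda = NULL,
                                nfolds = 10L, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(time), length(time) == length(event),
            alpha >= 0, alpha <= 1, nfolds >= 2)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  y <- survival::Surv(time, event)

  if (ncol(x) == 1L) {
    # glmnet requires >= 2 columns; a single-feature category is fitted
    # unpenalized (equivalent to the lambda -> 0 solution)
    fit <- survival::coxph(y ~ x, ties = "efron")
    beta <- stats::setNames(unname(stats::coef(fit)), colnames(x))
    return(list(beta = beta, lambda_selected = 0,
                lambda = 0, beta_path = matrix(beta, ncol = 1,
                                               dimnames = list(colnames(x), NULL)),
                cvm = NULL, alpha = alpha))
  }

  single <- !is.null(lambda) && length(lambda) == 1L
  if (single) {
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = alpha,
                          standardize = FALSE, thresh = 1e-14,
                          maxit = 1e7)
    beta <- drop(as.matrix(stats::coef(fit, s = lambda[1], exact = TRUE,
                                       x = x, y = y, alpha = alpha,
                                       standardize = FALSE,
                                       thresh = 1e-14, maxit = 1e7)))
    return(list(beta = stats::setNames(beta, colnames(x)),
                lambda_selected = lambda[1],
                lambda = lambda[1],
                beta_path = matrix(beta, ncol = 1,
                                   dimnames = list(colnames(x), NULL)),
                cvm = NULL, alpha = alpha))
  }

  foldid <- make_foldid(event, nfolds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha,
                          lambda = lambda, foldid = foldid,
                          standardize = FALSE, thresh = 1e-10,
                          maxit = 1e6)
  beta_path <- as.matrix(cv$glmnet.fit$beta)
  beta <- drop(as.matrix(stats::coef(cv, s = "lambda.min")))
  list(beta = stats::setNames(beta, colnames(x)),
       lambda_selected = cv$lambda.min,
       lambda = cv$lambda,
       beta_path = beta_path,
       cvm = cv$cvm,
       alpha = alpha)
}

#' Fit the per-category LRE risk-score models (step 1)
#'
#' One elastic-net Cox fit per biomarker category, restricted to that
#' category's standardized biomarkers, with the liver-related event (LRE) as
#' outcome on the follow-up timescale. Stores per-category coefficients, the
#' selected penalties, the training standardization parameters, and the
#' training score means used for centering.
#'
#' @param cohort a `lai_cohort` with `lre`/`lre_time`.
#' @param spec a [lai_feature_spec()].
#' @param alpha elastic-net mixing parameter, default 0.5.
#' @param nfolds CV folds, default 10.
#' @param seed integer seed for fold assignment.
#' @return An object of class `lai_risk_scores`.
#' @export
fit_risk_scores <- function(cohort, spec = lai_feature_spec("lai13"),
                            alpha = 0.5, nfolds = 10L, seed = 1L) {
  if (!length(spec$categories)) stop("feature spec has no categories",
                                     call. = FALSE)
  std <- standardize_features(cohort, spec)
  models <- list()
  for (cc in spec$categories) {
    markers <- spec$biomarkers[spec$grouping == cc]
    if (!length(markers)) {
      stop("category with zero active biomarkers: ", cc, call. = FALSE)
    }
    fit <- fit_elastic_net_cox(std$x[, markers, drop = FALSE],
                               cohort$lre_time, cohort$lre,
                               alpha = alpha, nfolds = nfolds, seed = seed)
    score <- drop(std$x[, markers, drop = FALSE] %*% fit$beta)
    models[[cc]] <- list(markers = markers, beta = fit$beta,
                         lambda = fit$lambda_selected, m = mean(score))
  }
  structure(list(models = models, standardization = std$params,
                 alpha = alpha, nfolds = as.integer(nfolds),
                 seed = as.integer(seed), spec = spec),
            class = "lai_risk_scores")
}

#' Compute centered per-category risk scores
#'
#' `s_c = beta_c' z - m_c`, where `z` uses the training standardization and
#' `m_c` is the training score mean, so every score has mean zero in the
#' training cohort.
#'
#' @param model a [fit_risk_scores()] result.
#' @param cohort cohort with the active biomarkers.
#' @return numeric matrix, one column per category.
#' @export
compute_risk_scores <- function(model, cohort) {
  stopifnot(inherits(model, "lai_risk_scores"))
  std <- standardize_features(cohort, model$spec,
                              params = model$standardization)
  s <- sapply(model$models, function(m) {
    drop(std$x[, m$markers, drop = FALSE] %*% m$beta) - m$m
  })
  if (is.null(dim(s))) s <- matrix(s, nrow = 1,
                                   dimnames = list(NULL, names(model$models)))
  s
}

#' @export
print.lai_risk_scores <- function(x, ...) {
  cat("Per-category LRE risk scores (elastic net, alpha =", x$alpha, ")\n")
  for (cc in names(x$models)) {
    m <- x$models[[cc]]
    cat(sprintf("  %-10s lambda = %.4g, beta: %s\n", cc, m$lambda,
                paste(sprintf("%s=%.3f", names(m$beta), m$beta),
                      collapse = ", ")))
  }
  invisible(x)
}
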