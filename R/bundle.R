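LAI_BUNDLE_SCHEMA <- "lai-bundle/1"

#' Serialize a fitted Liver Aging Index model to JSON
#'
#' Writes everything needed to apply the model to new cohorts — the feature
#' spec, per-category risk-score coefficients with standardization and
#' centering, the null/full Gompertz parameters, the training quartile
#' thresholds, and provenance — under an explicit `schema_version`. Numeric
#' fields round-trip to full double precision.
#'
#' @param model a `lai_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_lai_bundle <- function(model, path) {
  stopifnot(inherits(model, "lai_model"))
  th <- model$thresholds
  if (th["q1"] > th["q3"]) {
    stop("invalid bundle: quartile thresholds Q1 > Q3; refusing to write",
         call. = FALSE)
  }
  ser_gomp <- function(g) {
    list(strata = g$strata,
         b0 = as.list(g$b0), gamma = as.list(g$gamma),
         mrdt = as.list(g$mrdt),
         beta = as.list(g$beta),
         se_b0 = as.list(g$se_b0), se_gamma = as.list(g$se_gamma),
         se_beta = as.list(g$se_beta),
         gamma_fixed = g$gamma_fixed,
         boundary = as.list(g$boundary),
         loglik = g$loglik, gradient_norm = g$gradient_norm,
         iterations = g$iterations, n = g$n, events = g$events)
  }
  ser_rs <- function(rs) {
    list(models = lapply(rs$models, function(m) {
      list(markers = m$markers, beta = as.list(m$beta),
           lambda = m$lambda, m = m$m)
    }),
    standardization = list(mean = as.list(rs$standardization$mean),
                           sd = as.list(rs$standardization$sd)),
    alpha = rs$alpha, nfolds = rs$nfolds, seed = rs$seed)
  }
  obj <- list(
    schema_version = LAI_BUNDLE_SCHEMA,
    feature_spec = list(variant = model$spec$variant,
                        biomarkers = model$spec$biomarkers,
                        grouping = as.list(model$spec$grouping),
                        transforms = as.list(model$spec$transforms),
                        sex_stratified = model$spec$sex_stratified,
                        age_bounds = model$spec$age_bounds),
    fits = lapply(model$fits, function(f) {
      list(risk_scores = ser_rs(f$risk_scores),
           null_model = ser_gomp(f$null_model),
           full_model = ser_gomp(f$full_model),
           active_scores = f$active_scores)
    }),
    thresholds = as.list(model$thresholds),
    training = model$training,
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a Liver Aging Index model bundle
#'
#' @param path JSON path written by [write_lai_bundle()].
#' @return a `lai_model`.
#' @export
read_lai_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("bundle is not parseable JSON (truncated or corrupt): ",
                         conditionMessage(e), call. = FALSE)
                  })
  required <- c("schema_version", "feature_spec", "fits", "thresholds",
                "provenance")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop("bundle is missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(obj$schema_version, LAI_BUNDLE_SCHEMA)) {
    stop("bundle schema_version '", obj$schema_version,
         "' does not match supported '", LAI_BUNDLE_SCHEMA,
         "'; refusing to reinterpret", call. = FALSE)
  }
  fs <- obj$feature_spec
  spec <- lai_feature_spec(fs$variant,
                           biomarkers = unlist(fs$biomarkers),
                           grouping = unlist(fs$grouping),
                           transforms = unlist(fs$transforms),
                           sex_stratified = fs$sex_stratified,
                           age_bounds = unlist(fs$age_bounds))
  de_gomp <- function(g) {
    nv <- function(x) {
      v <- vapply(x, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
                  numeric(1))
      v
    }
    structure(list(
      strata = unlist(g$strata),
      b0 = nv(g$b0), gamma = nv(g$gamma), mrdt = nv(g$mrdt),
      beta = if (length(g$beta)) nv(g$beta) else numeric(0),
      se_b0 = nv(g$se_b0), se_gamma = nv(g$se_gamma),
      se_beta = if (length(g$se_beta)) nv(g$se_beta) else numeric(0),
      gamma_fixed = isTRUE(g$gamma_fixed),
      boundary = vapply(g$boundary, isTRUE, logical(1)),
      loglik = as.numeric(g$loglik),
      gradient_norm = as.numeric(g$gradient_norm),
      iterations = as.integer(g$iterations),
      n = as.integer(g$n), events = as.integer(g$events)
    ), class = "gompertz_ph")
  }
  de_rs <- function(rs) {
    structure(list(
      models = lapply(rs$models, function(m) {
        list(markers = unlist(m$markers),
             beta = vapply(m$beta, as.numeric, numeric(1)),
             lambda = as.numeric(m$lambda), m = as.numeric(m$m))
      }),
      standardization = list(
        mean = vapply(rs$standardization$mean, as.numeric, numeric(1)),
        sd = vapply(rs$standardization$sd, as.numeric, numeric(1))
      ),
      alpha = as.numeric(rs$alpha), nfolds = as.integer(rs$nfolds),
      seed = as.integer(rs$seed), spec = spec
    ), class = "lai_risk_scores")
  }
  fits <- lapply(obj$fits, function(f) {
    list(risk_scores = de_rs(f$risk_scores),
         null_model = de_gomp(f$null_model),
         full_model = de_gomp(f$full_model),
         active_scores = unlist(f$active_scores))
  })
  structure(list(
    spec = spec,
    fits = fits,
    thresholds = unlist(obj$thresholds)[c("q1", "q3")],
    training = lapply(obj$training, function(v) v),
    provenance = obj$provenance
  ), class = "lai_model")
}
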