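#' @keywords internal
"_PACKAGE"

#' The 13-biomarker liver aging panel
#'
#' Canonical biomarker names, units, and default category grouping used by
#' the Liver Aging Index. Units are fixed (kg/m2, mmHg, mmol/L, U/L, dB/m,
#' kPa) and are documented, never auto-converted.
#'
#' @format `lai_biomarkers()` returns a data.frame with columns `marker`,
#'   `unit`, and `category`.
#' @export
lai_biomarkers <- function() {
  data.frame(
    marker = c("bmi", "sbp", "dbp",
               "glucose", "tc", "tg", "hdl", "ldl",
               "alt", "ast", "ggt",
               "fap", "lsm"),
    unit = c("kg/m2", "mmHg", "mmHg",
             "mmol/L", "mmol/L", "mmol/L", "mmol/L", "mmol/L",
             "U/L", "U/L", "U/L",
             "dB/m", "kPa"),
    category = c("clinical", "clinical", "clinical",
                 "metabolic", "metabolic", "metabolic", "metabolic", "metabolic",
                 "enzyme", "enzyme", "enzyme",
                 "imaging", "imaging"),
    stringsAsFactors = FALSE
  )
}

#' Feature specification for a Liver Aging Index variant
#'
#' Declares which biomarkers are active, how they are grouped into categories
#' for the per-category risk scores, which are log-transformed before
#' standardization, and whether the whole model is fitted stratified by sex.
#'
#' The `"lai13"` variant uses all 13 biomarkers in four categories
#' (clinical: BMI, SBP, DBP; metabolic: glucose, TC, TG, HDL-C, LDL-C;
#' enzyme: ALT, AST, GGT; imaging: FAP, LSM) with sex-stratified Gompertz
#' baselines and shared risk-score coefficients. The `"lai5"` variant keeps
#' only the five hepatic biomarkers (ALT, AST, GGT, FAP, LSM) in two
#' categories and fits the entire pipeline separately per sex.
#'
#' @param variant `"lai13"` or `"lai5"`.
#' @param biomarkers optional character vector overriding the active panel.
#' @param grouping optional named character vector mapping each active
#'   biomarker to a category label.
#' @param transforms optional named character vector mapping biomarkers to
#'   `"identity"` or `"log"`; defaults to identity for all.
#' @param sex_stratified logical; fit the full pipeline separately per sex.
#'   Defaults to `FALSE` for `"lai13"` and `TRUE` for `"lai5"`.
#' @param age_bounds numeric length-2; admissible chronological age range in
#'   years, default `c(45, 95)`.
#' @return An object of class `lai_feature_spec`.
#' @examples
#' spec <- lai_feature_spec("lai13")
#' table(spec$grouping)
#' @export
lai_feature_spec <- function(variant = c("lai13", "lai5"),
                             biomarkers = NULL,
                             grouping = NULL,
                             transforms = NULL,
                             sex_stratified = NULL,
                             age_bounds = c(45, 95)) {
  variant <- match.arg(variant)
  panel <- lai_biomarkers()
  if (is.null(biomarkers)) {
    biomarkers <- if (variant == "lai5") {
      c("alt", "ast", "ggt", "fap", "lsm")
    } else {
      panel$marker
    }
  }
  biomarkers <- as.character(biomarkers)
  if (anyDuplicated(biomarkers)) {
    stop("duplicate biomarkers in feature spec", call. = FALSE)
  }
  if (is.null(grouping)) {
    known <- stats::setNames(panel$category, panel$marker)
    if (!all(biomarkers %in% names(known))) {
      stop("custom biomarkers require an explicit `grouping`", call. = FALSE)
    }
    grouping <- known[biomarkers]
  }
  grouping <- grouping[biomarkers]
  if (any(is.na(grouping)) || is.null(names(grouping))) {
    stop("every active biomarker must belong to exactly one category",
         call. = FALSE)
  }
  if (is.null(transforms)) {
    transforms <- stats::setNames(rep("identity", length(biomarkers)), biomarkers)
  } else {
    tr <- stats::setNames(rep("identity", length(biomarkers)), biomarkers)
    bad <- setdiff(names(transforms), biomarkers)
    if (length(bad)) {
      stop("transform declared for inactive biomarker: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tr[names(transforms)] <- transforms
    transforms <- tr
  }
  if (!all(transforms %in% c("identity", "log"))) {
    stop("transforms must be 'identity' or 'log'", call. = FALSE)
  }
  if (is.null(sex_stratified)) sex_stratified <- (variant == "lai5")
  stopifnot(is.numeric(age_bounds), length(age_bounds) == 2L,
            age_bounds[1] < age_bounds[2])
  structure(
    list(variant = variant,
         biomarkers = biomarkers,
         grouping = grouping,
         transforms = transforms,
         categories = unique(unname(grouping)),
         sex_stratified = isTRUE(sex_stratified),
         age_bounds = as.numeric(age_bounds)),
    class = "lai_feature_spec"
  )
}

#' @export
print.lai_feature_spec <- function(x, ...) {
  cat("Liver Aging Index feature spec (", x$variant, ")\n", sep = "")
  cat("  biomarkers:", length(x$biomarkers), "in",
      length(x$categories), "categories\n")
  for (cc in x$categories) {
    cat("   ", cc, ":", paste(x$biomarkers[x$grouping == cc], collapse = ", "),
        "\n")
  }
  logs <- names(x$transforms)[x$transforms == "log"]
  if (length(logs)) cat("  log-transformed:", paste(logs, collapse = ", "), "\n")
  cat("  sex-stratified:", x$sex_stratified,
      " age range: [", x$age_bounds[1], ",", x$age_bounds[2], "]\n")
  invisible(x)
}
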