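#' Validate and canonicalize a cohort table
#'
#' Applies the schema and row-level exclusion rules to a raw data.frame:
#' sex labels are canonicalized to `female`/`male`; rows are dropped (and
#' counted, by reason) when chronological age falls outside the declared
#' range, an active biomarker is missing (complete-case analysis, no
#' imputation), follow-up is missing or non-positive, event indicators or
#' event times are inconsistent (indicators outside {0,1}, event time after
#' follow-up, liver-related death without death), a log-transformed biomarker
#' is non-positive, or a survey weight is non-positive.
#'
#' Exclusion accounting always satisfies
#' `n_input == n_retained + sum(exclusions)` ; each row is counted once,
#' under the first failing rule in the order above.
#'
#' @param df data.frame with columns `subject_id`, `age`, `sex`, the active
#'   biomarkers, `followup_time`, `death`, `lre`, `lre_time`, `lrm`,
#'   `lrm_time`; optional `weight` (default 1), `region`, `education`,
#'   `marital_status`.
#' @param spec a [lai_feature_spec()].
#' @param age_bounds admissible age range; defaults to the spec's.
#' @return A data.frame of class `lai_cohort` with attribute `exclusions`
#'   (named integer vector of per-reason drop counts).
#' @export
as_lai_cohort <- function(df, spec = lai_feature_spec("lai13"),
                          age_bounds = spec$age_bounds) {
  stopifnot(is.data.frame(df), inherits(spec, "lai_feature_spec"))
  required <- c("subject_id", "age", "sex", spec$biomarkers,
                "followup_time", "death", "lre", "lre_time", "lrm", "lrm_time")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(df)
  df$subject_id <- as.character(df$subject_id)
  if (!"weight" %in% names(df)) df$weight <- 1
  sex <- canonicalize_sex(df$sex)

  num <- function(v) suppressWarnings(as.numeric(v))
  age <- num(df$age)
  fu <- num(df$followup_time)
  death <- num(df$death); lre <- num(df$lre); lrm <- num(df$lrm)
  lre_time <- num(df$lre_time); lrm_time <- num(df$lrm_time)
  weight <- num(df$weight)
  bm <- as.matrix(as.data.frame(lapply(df[spec$biomarkers], num)))

  ind01 <- function(v) !is.na(v) & (v == 0 | v == 1)
  tol <- 1e-9
  bad_sex <- is.na(sex)
  bad_age <- !bad_sex & (is.na(age) | age < age_bounds[1] | age > age_bounds[2])
  bad_feat <- !bad_sex & !bad_age & rowSums(is.na(bm)) > 0
  log_markers <- names(spec$transforms)[spec$transforms == "log"]
  bad_pos <- rep(FALSE, n_input)
  if (length(log_markers)) {
    bad_pos <- rowSums(bm[, log_markers, drop = FALSE] <= 0, na.rm = TRUE) > 0
  }
  bad_pos <- !bad_sex & !bad_age & !bad_feat & bad_pos
  prev <- bad_sex | bad_age | bad_feat | bad_pos
  bad_fu <- !prev & (is.na(fu) | fu <= 0)
  prev <- prev | bad_fu
  bad_event <- !prev & !(ind01(death) & ind01(lre) & ind01(lrm) &
                           !is.na(lre_time) & !is.na(lrm_time) &
                           lre_time <= fu + tol & lrm_time <= fu + tol &
                           !(lrm == 1 & death == 0))
  prev <- prev | bad_event
  bad_weight <- !prev & (is.na(weight) | weight <= 0)

  keep <- !(prev | bad_weight)
  exclusions <- c(invalid_sex = sum(bad_sex),
                  age_out_of_range = sum(bad_age),
                  missing_feature = sum(bad_feat),
                  nonpositive_biomarker = sum(bad_pos),
                  invalid_followup = sum(bad_fu),
                  invalid_event = sum(bad_event),
                  nonpositive_weight = sum(bad_weight))
  exclusions <- exclusions[exclusions > 0]
  stopifnot(n_input == sum(keep) + sum(exclusions))
  if (!any(keep)) {
    stop("no valid rows remain after exclusions (",
         paste(names(exclusions), exclusions, sep = "=", collapse = ", "),
         ")", call. = FALSE)
  }

  out <- data.frame(subject_id = df$subject_id, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  for (j in spec$biomarkers) out[[j]] <- bm[, j]
  out$followup_time <- fu
  out$death <- as.integer(death); out$lre <- as.integer(lre)
  out$lre_time <- lre_time
  out$lrm <- as.integer(lrm); out$lrm_time <- lrm_time
  out$weight <- weight
  for (extra in c("region", "education", "marital_status")) {
    if (extra %in% names(df)) out[[extra]] <- as.character(df[[extra]])
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, exclusions = as.integer(exclusions) |>
              stats::setNames(names(exclusions)),
            class = c("lai_cohort", "data.frame"))
}

canonicalize_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("0", "f", "female")] <- "female"
  out[s %in% c("1", "m", "male")] <- "male"
  out
}

#' Per-reason exclusion counts of a validated cohort
#'
#' @param cohort a `lai_cohort`.
#' @return Named integer vector (empty when nothing was excluded).
#' @export
exclusion_log <- function(cohort) {
  ex <- attr(cohort, "exclusions")
  if (is.null(ex)) integer(0) else ex
}

#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, header required, decimal point. Units follow the
#' panel definition in [lai_biomarkers()] and are not converted. Sex accepts
#' 0/1, F/M, or female/male. Rows violating the schema invariants are dropped
#' and counted; see [as_lai_cohort()].
#'
#' @param path CSV file path.
#' @param spec a [lai_feature_spec()].
#' @inheritParams as_lai_cohort
#' @return A `lai_cohort`.
#' @export
read_cohort_csv <- function(path, spec = lai_feature_spec("lai13"),
                            age_bounds = spec$age_bounds) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  as_lai_cohort(df, spec, age_bounds)
}

#' Write a cohort CSV
#'
#' @param cohort a `lai_cohort` (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.lai_cohort <- function(x, ...) {
  ex <- exclusion_log(x)
  cat("Liver aging cohort: ", nrow(x), " subjects (",
      sum(x$sex == "female"), " female), ",
      sum(x$death), " deaths, ", sum(x$lre), " LREs, ",
      sum(x$lrm), " LRMs\n", sep = "")
  cat("  age ", round(min(x$age), 1), "-", round(max(x$age), 1),
      " years, median follow-up ",
      round(stats::median(x$followup_time), 2), " years\n", sep = "")
  if (length(ex)) {
    cat("  excluded at validation:",
        paste(names(ex), ex, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
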