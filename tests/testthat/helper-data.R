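# Shared fixture builders (all data generated in code).

# Minimal hand-built cohort data.frame with valid defaults; any column can
# be overridden.
make_cohort_df <- function(n = 5, ...) {
  bm <- lai_biomarkers()
  df <- data.frame(subject_id = paste0("P", seq_len(n)),
                   age = seq(50, 70, length.out = n),
                   sex = rep(c("female", "male"), length.out = n),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bm))) {
    df[[bm$marker[i]]] <- rep(default_biomarker_params()$mu[i], n)
  }
  df$followup_time <- 5
  df$death <- rep(c(0L, 1L), length.out = n)
  df$lre <- 0L
  df$lre_time <- 5
  df$lrm <- 0L
  df$lrm_time <- 5
  overrides <- list(...)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  df
}

# Small simulated training cohort used across fitting tests.
small_sim <- function(n = 4000, seed = 11, ...) {
  simulate_cohort(sim_config(n = n, seed = seed, ...))
}

# Closed-form inverse-transform Gompertz event-age draw (age timescale,
# left-truncated at a0); used to build survival fixtures directly.
sample_gompertz_age <- function(a0, b0, gamma, lp, E) {
  a0 + log1p(gamma * E * exp(-(b0 + lp + gamma * a0))) / gamma
}

# Hand-made gompertz_ph objects for transformation identity tests.
fake_gompertz <- function(b0, gamma, beta = numeric(0), strata = "all") {
  structure(list(strata = strata,
                 b0 = stats::setNames(rep(b0, length(strata)), strata),
                 gamma = stats::setNames(rep(gamma, length(strata)), strata),
                 mrdt = stats::setNames(rep(log(2) / gamma, length(strata)),
                                        strata),
                 beta = beta,
                 boundary = stats::setNames(rep(FALSE, length(strata)),
                                            strata),
                 loglik = NA_real_, n = 0L, events = 0L),
            class = "gompertz_ph")
}
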