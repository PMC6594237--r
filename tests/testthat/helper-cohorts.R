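# Cohort builders used across the suite. All dates are integer days from the
# study origin; index defaults to day 0 so date arithmetic is easy to eyeball.

mk_patients <- function(ehr, gold, last, index = 0, arm = "control",
                        id = NULL) {
  n <- max(length(ehr), length(gold), length(last))
  tibble::tibble(
    patient_id = id %||% sprintf("T%03d", seq_len(n)),
    index_date = as.integer(rep_len(index, n)),
    arm = rep_len(arm, n),
    ehr_death_date = as.integer(rep_len(ehr, n)),
    gold_death_date = as.integer(rep_len(gold, n)),
    last_activity_date = as.integer(rep_len(last, n))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Six patients covering the four presence patterns:
# both, both, ehr-only, gold-only, gold-only, neither -> A, A, B, C, C, D
toy_cohort <- function() {
  mk_patients(
    ehr  = c(100L, 90L, 50L, NA, NA, NA),
    gold = c(100L, 95L, NA, 80L, 120L, NA),
    last = c(100L, 95L, 60L, 30L, 110L, 40L)
  )
}

# Cohort with exact cell counts (a, b, c, d); dead patients die on day 400.
cohort_with_counts <- function(a, b, c, d) {
  mk_patients(
    ehr = c(rep(400L, a), rep(300L, b), rep(NA, c), rep(NA, d)),
    gold = c(rep(400L, a), rep(NA, b), rep(400L, c), rep(NA, d)),
    last = c(rep(400L, a), rep(350L, b), rep(200L, c), rep(500L, d)),
    arm = "control"
  )
}

# Small default simulated cohort reused by several files.
small_cohort <- function(seed = 42, n = 600, ...) {
  simulate_cohort(cohort_config(n_per_arm = n, seed = seed, ...))
}
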