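## Patient-level cohort tables and mortality-capture classification.
##
## A cohort is a tibble with one row per patient and (at least) the columns
##   patient_id          opaque string
##   index_date          integer days from the study origin
##   arm                 arm label, e.g. "experimental" / "control"
##   ehr_death_date      integer days, NA when the EHR has no death record
##   gold_death_date     integer days, NA when the gold standard has no death
##   last_activity_date  integer days (last structured visit/administration)
## Classification compares presence of the two death dates: each patient falls
## in exactly one capture cell, A (both), B (EHR only), C (gold only),
## D (neither). Date values never affect the cell.

cohort_columns <- c(
  "patient_id", "index_date", "arm",
  "ehr_death_date", "gold_death_date", "last_activity_date"
)

#' Validate a patient-level cohort table
#'
#' Checks the structural invariants every downstream analysis relies on:
#' required columns, non-missing index/arm/activity dates, activity on or
#' after the index date, gold-standard deaths on or after the index date with
#' no structured activity recorded after them, and EHR deaths on or after the
#' index date.
#'
#' @param cohort A data frame with the cohort columns described above.
#' @return `cohort` as a tibble, invisibly, so calls can be piped.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) {
    abort("`cohort` must be a data frame.", class = "mortsens_error_input")
  }
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    abort(
      paste0("`cohort` is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "mortsens_error_input"
    )
  }
  if (nrow(cohort) == 0) {
    abort("`cohort` must contain at least one patient.",
      class = "mortsens_error_empty"
    )
  }
  cohort <- as_tibble(cohort)
  with(cohort, {
    if (anyNA(index_date) || anyNA(last_activity_date) || anyNA(arm)) {
      abort("index_date, arm and last_activity_date must be non-missing.",
        class = "mortsens_error_input"
      )
    }
    bad <- last_activity_date < index_date
    if (any(bad)) {
      abort(
        sprintf("%d patient(s) have last_activity_date before index_date.", sum(bad)),
        class = "mortsens_error_invariant"
      )
    }
    gold <- !is.na(gold_death_date)
    if (any(gold & cohort$gold_death_date < index_date)) {
      abort("gold_death_date before index_date.", class = "mortsens_error_invariant")
    }
    if (any(gold & cohort$last_activity_date > cohort$gold_death_date)) {
      abort("last_activity_date after gold_death_date.",
        class = "mortsens_error_invariant"
      )
    }
    ehr <- !is.na(ehr_death_date)
    if (any(ehr & cohort$ehr_death_date < index_date)) {
      abort("ehr_death_date before index_date.", class = "mortsens_error_invariant")
    }
  })
  invisible(cohort)
}

## Vectorised presence -> cell mapping; the core of the classification.
cell_of <- function(ehr_present, gold_present) {
  factor(
    dplyr::case_when(
      ehr_present & gold_present ~ "A",
      ehr_present & !gold_present ~ "B",
      !ehr_present & gold_present ~ "C",
      TRUE ~ "D"
    ),
    levels = c("A", "B", "C", "D")
  )
}

#' Classify mortality capture against the gold standard
#'
#' Adds a `cell` column assigning each patient to one capture cell:
#' * **A** (true positive) — death recorded in both sources,
#' * **B** (false positive) — death in the EHR only,
#' * **C** (false negative) — death in the gold standard only,
#' * **D** (true negative) — death in neither.
#'
#' Only the *presence* of the two death dates matters; patients whose
#' recorded dates disagree in value are still cell A.
#'
#' @inheritParams validate_cohort
#' @return The cohort tibble with a `cell` factor column (levels A, B, C, D).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_arm = 100, seed = 1))
#' dplyr::count(classify_mortality(cohort), cell)
#' @export
classify_mortality <- function(cohort) {
  cohort <- validate_cohort(cohort)
  dplyr::mutate(
    cohort,
    cell = cell_of(!is.na(.data$ehr_death_date), !is.na(.data$gold_death_date))
  )
}

#' Construct confusion-cell counts
#'
#' @param a,b,c,d Nonnegative integer patient counts: true positives (death in
#'   both sources), false positives (EHR only), false negatives (gold only),
#'   true negatives (neither).
#' @return A `confusion_counts` object (one-row tibble with columns
#'   `a`, `b`, `c`, `d`, `n`).
#' @examples
#' confusion_counts(6157, 136, 639, 3263)
#' @export
confusion_counts <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Cell counts must be nonnegative integers.", class = "mortsens_error_input")
  }
  out <- tibble(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                d = as.integer(d), n = as.integer(a + b + c + d))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Tabulate capture cells for a cohort
#'
#' Counts patients in each capture cell. The counts partition the cohort:
#' `a + b + c + d` equals the number of patients, whatever the row order.
#'
#' @inheritParams validate_cohort
#' @return A [confusion_counts()] object.
#' @export
tabulate_cells <- function(cohort) {
  if (is.data.frame(cohort) && nrow(cohort) == 0) {
    abort("Cannot tabulate an empty cohort.", class = "mortsens_error_empty")
  }
  if (!"cell" %in% names(cohort)) {
    cohort <- classify_mortality(cohort)
  }
  k <- table(cohort$cell)
  confusion_counts(k[["A"]], k[["B"]], k[["C"]], k[["D"]])
}

#' Death-capture sensitivity and specificity
#'
#' Sensitivity is the fraction of gold-standard deaths also recorded in the
#' EHR, `a / (a + c)`; specificity is the fraction of gold-standard survivors
#' with no EHR death record, `d / (b + d)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return A one-row tibble with columns `sensitivity` and `specificity`.
#' @examples
#' capture_metrics(confusion_counts(6157, 136, 639, 3263))
#' @export
capture_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$a + counts$c == 0) {
    abort("Sensitivity undefined: no gold-standard deaths (a + c = 0).",
      class = "mortsens_error_undefined"
    )
  }
  if (counts$b + counts$d == 0) {
    abort("Specificity undefined: no gold-standard survivors (b + d = 0).",
      class = "mortsens_error_undefined"
    )
  }
  tibble(
    sensitivity = counts$a / (counts$a + counts$c),
    specificity = counts$d / (counts$b + counts$d)
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "Mortality-capture cells (n = %d)\n  A (true +): %d   B (false +): %d   C (false -): %d   D (true -): %d\n",
    x$n, x$a, x$b, x$c, x$d
  ))
  if (x$a + x$c > 0 && x$b + x$d > 0) {
    m <- capture_metrics(x)
    cat(sprintf(
      "  sensitivity %.1f%%   specificity %.1f%%\n",
      100 * m$sensitivity, 100 * m$specificity
    ))
  }
  invisible(x)
}

#' Read and write cohort CSV files
#'
#' The on-disk format is a headered CSV with columns `patient_id`,
#' `index_date`, `arm`, `ehr_death_date`, `gold_death_date`,
#' `last_activity_date`; dates are integer days from the study origin and an
#' empty field means the death date is absent.
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      index_date = readr::col_integer(),
      arm = readr::col_character(),
      ehr_death_date = readr::col_integer(),
      gold_death_date = readr::col_integer(),
      last_activity_date = readr::col_integer()
    )
  )
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @inheritParams validate_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[, intersect(c(cohort_columns, "cell"), names(cohort))],
    path, na = ""
  )
  invisible(path)
}

#' Serialise confusion counts and capture metrics to JSON
#'
#' @param counts A [confusion_counts()] object.
#' @param path Output path for a JSON object
#'   `{a, b, c, d, sensitivity, specificity}`.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(counts, path) {
  stopifnot(inherits(counts, "confusion_counts"))
  m <- capture_metrics(counts)
  jsonlite::write_json(
    list(
      a = counts$a, b = counts$b, c = counts$c, d = counts$d,
      sensitivity = m$sensitivity, specificity = m$specificity
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
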