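## Published reference values bundled with the package.

#' Reference median-OS table from a published aNSCLC validation study
#'
#' Median overall survival (months) reported for six advanced-NSCLC exposure
#' groups in a large US community-oncology EHR cohort linked to a
#' gold-standard national death index, at four death-capture sensitivity
#' levels: two simulated degradations (63.4% and 72.5%), the observed EHR
#' source (90.6%), and the gold standard itself. `bias_pct` is the percent
#' bias of each median against the gold-standard median as published
#' (`NA` for the gold rows, which are their own benchmark). Used as worked-
#' example input for [percent_bias()] arithmetic; the medians themselves are
#' not reproducible without the proprietary source data.
#'
#' @return A tibble with columns `group`, `sensitivity_label`, `mos_months`,
#'   `bias_pct`.
#' @examples
#' tbl <- mos_benchmark_table()
#' gold <- dplyr::filter(tbl, sensitivity_label == "gold")
#' @export
mos_benchmark_table <- function() {
  readr::read_csv(
    system.file("extdata", "nsclc_mos_benchmarks.csv", package = "mortsens"),
    col_types = readr::cols(
      group = readr::col_character(),
      sensitivity_label = readr::col_character(),
      mos_months = readr::col_double(),
      bias_pct = readr::col_double()
    )
  )
}

#' Reference mortality-capture cell counts
#'
#' Cell counts for the same published aNSCLC cohort: 6157 true positives,
#' 136 false positives, 639 false negatives and 3263 true negatives
#' (N = 10 195), giving 90.6% death-capture sensitivity.
#'
#' @return A [confusion_counts()] object.
#' @examples
#' capture_metrics(reference_cell_counts())
#' @export
reference_cell_counts <- function() {
  confusion_counts(6157, 136, 639, 3263)
}
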