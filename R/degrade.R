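## Sensitivity degradation by random reclassification.
##
## Lowering the death-capture sensitivity of a classified cohort: a random
## fraction of true positives (cell A) lose their EHR death date and become
## false negatives (cell C). Because such a patient would no longer be seen
## to die in EHR-sourced analyses, their last-activity censoring date is
## replaced by a censor date drawn uniformly between index and the (still
## known) gold-standard death date. Repeating the draw many times and taking
## the median / 2.5th / 97.5th percentiles of a statistic yields a
## simulation point estimate with a percentile confidence interval.

#' Configuration for a sensitivity-degradation study
#'
#' @param fraction_p Share of cell-A patients reclassified to cell C, in
#'   \[0, 1\].
#' @param n_iterations Number of independent degradation draws (default 1000).
#' @param seed Master seed; each iteration runs on its own substream derived
#'   from it, so runs are reproducible and iterations independent.
#' @return A `degradation_config` list.
#' @export
degradation_config <- function(fraction_p, n_iterations = 1000, seed = 1L) {
  if (!is.numeric(fraction_p) || fraction_p < 0 || fraction_p > 1) {
    abort("`fraction_p` must lie in [0, 1].", class = "mortsens_error_config")
  }
  if (n_iterations < 1 || n_iterations != round(n_iterations)) {
    abort("`n_iterations` must be a positive integer.",
      class = "mortsens_error_config"
    )
  }
  structure(
    list(
      fraction_p = fraction_p, n_iterations = as.integer(n_iterations),
      seed = as.integer(seed)
    ),
    class = "degradation_config"
  )
}

#' Reclassify a random fraction of captured deaths as missed
#'
#' Performs one degradation draw: exactly `round(fraction_p * |A|)` distinct
#' cell-A patients (round-half-to-even) lose their EHR death date, becoming
#' cell C, and have their last-activity date replaced by a censor date drawn
#' uniformly on `[index_date, gold_death_date)`. All other patients — and the
#' input cohort — are left untouched.
#'
#' @param cohort A classified cohort (see [classify_mortality()]); an
#'   unclassified cohort is classified on the fly.
#' @param fraction_p Share of eligible cell-A patients to reclassify.
#' @param arms Optional character vector restricting reclassification to
#'   cell-A patients of these arms (used for external-control analyses where
#'   only the EHR-sourced control arm degrades).
#' @param seed Optional seed for this single draw.
#' @return The degraded cohort tibble, reclassified `cell` column included.
#' @export
degrade_cohort <- function(cohort, fraction_p, arms = NULL, seed = NULL) {
  if (!is.numeric(fraction_p) || fraction_p < 0 || fraction_p > 1) {
    abort("`fraction_p` must lie in [0, 1].", class = "mortsens_error_config")
  }
  if (!"cell" %in% names(cohort)) {
    cohort <- classify_mortality(cohort)
  }
  with_seed(seed, {
    eligible <- which(
      cohort$cell == "A" & (is.null(arms) | cohort$arm %in% arms)
    )
    n_move <- round(fraction_p * length(eligible))
    if (n_move == 0) {
      return(cohort)
    }
    moved <- sample(eligible, n_move)
    idx <- cohort$index_date[moved]
    death <- cohort$gold_death_date[moved]
    # uniform on [index, death) in integer days
    censor <- idx + floor(runif(n_move) * (death - idx))
    cohort$ehr_death_date[moved] <- NA_integer_
    cohort$last_activity_date[moved] <- as.integer(censor)
    cohort$cell[moved] <- "C"
    cohort
  })
}

#' Expected sensitivity after degradation
#'
#' The analytic counterpart of [degrade_cohort()]: reclassifying a fraction
#' `p` of the `a` true positives leaves expected sensitivity
#' `(1 - p) * a / (a + c)`.
#'
#' @param counts A [confusion_counts()] object.
#' @param fraction_p Reclassified share of cell A.
#' @return Expected sensitivity as a fraction in \[0, 1\].
#' @examples
#' cells <- confusion_counts(6157, 136, 639, 3263)
#' expected_degraded_sensitivity(cells, 0.3) # 0.634
#' expected_degraded_sensitivity(cells, 0.2) # 0.725
#' @export
expected_degraded_sensitivity <- function(counts, fraction_p) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$a + counts$c == 0) {
    abort("No gold-standard deaths: sensitivity undefined.",
      class = "mortsens_error_undefined"
    )
  }
  if (fraction_p < 0 || fraction_p > 1) {
    abort("`fraction_p` must lie in [0, 1].", class = "mortsens_error_config")
  }
  (1 - fraction_p) * counts$a / (counts$a + counts$c)
}

#' Run a degradation simulation study
#'
#' Applies [degrade_cohort()] `n_iterations` times — fresh random selection
#' and fresh censor dates each iteration, all derived from the master seed —
#' and evaluates `statistic_fn` on every degraded cohort. The median across
#' iterations is the point estimate; the 2.5th and 97.5th percentiles form
#' the confidence interval.
#'
#' @inheritParams degrade_cohort
#' @param config A [degradation_config()].
#' @param statistic_fn Function of a (degraded) cohort returning a single
#'   numeric value or a named numeric vector (one summary row per name).
#' @param arms Optional arm restriction passed to [degrade_cohort()].
#' @return A `degradation_summary` object: `tidy()` returns the
#'   per-iteration draws, `glance()` the point estimate and percentile CI.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_arm = 200, seed = 7))
#' study <- run_degradation_study(
#'   cohort, degradation_config(0.3, n_iterations = 50, seed = 7),
#'   statistic_fn = function(x) capture_metrics(tabulate_cells(x))$sensitivity
#' )
#' glance(study)
#' @export
run_degradation_study <- function(cohort, config, statistic_fn, arms = NULL) {
  stopifnot(inherits(config, "degradation_config"), is.function(statistic_fn))
  if (!"cell" %in% names(cohort)) {
    cohort <- classify_mortality(cohort)
  }
  iter_seeds <- with_seed(
    config$seed,
    sample.int(.Machine$integer.max, config$n_iterations)
  )
  draws <- purrr::map(seq_len(config$n_iterations), function(i) {
    value <- tryCatch(
      statistic_fn(degrade_cohort(
        cohort, config$fraction_p,
        arms = arms, seed = iter_seeds[i]
      )),
      error = function(e) {
        abort(
          sprintf("statistic_fn failed at iteration %d: %s", i, conditionMessage(e)),
          class = "mortsens_error_iteration", parent = e
        )
      }
    )
    if (is.null(names(value))) {
      names(value) <- rep("statistic", length(value))
    }
    tibble(iteration = i, statistic = names(value), value = unname(value))
  })
  draws <- dplyr::bind_rows(draws)
  summary <- draws |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      point_estimate = median(.data$value),
      ci_lower = quantile(.data$value, 0.025, names = FALSE),
      ci_upper = quantile(.data$value, 0.975, names = FALSE),
      .groups = "drop"
    )
  structure(
    list(draws = draws, summary = summary, config = config),
    class = "degradation_summary"
  )
}

#' @export
print.degradation_summary <- function(x, ...) {
  cat(sprintf(
    "Degradation study: fraction_p = %.2f, %d iterations, seed %d\n",
    x$config$fraction_p, x$config$n_iterations, x$config$seed
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname run_degradation_study
#' @param x A `degradation_summary` object.
#' @param ... Unused.
#' @export
tidy.degradation_summary <- function(x, ...) x$draws

#' @rdname run_degradation_study
#' @export
glance.degradation_summary <- function(x, ...) {
  dplyr::mutate(x$summary,
    fraction_p = x$config$fraction_p,
    n_iterations = x$config$n_iterations
  )
}

#' @rdname run_degradation_study
#' @param object A `degradation_summary` object.
#' @export
autoplot.degradation_summary <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(
      data = object$summary,
      ggplot2::aes(xintercept = .data$point_estimate), linewidth = 0.8
    ) +
    ggplot2::geom_vline(
      data = tidyr::pivot_longer(
        object$summary, c("ci_lower", "ci_upper"),
        names_to = "bound", values_to = "x"
      ),
      ggplot2::aes(xintercept = .data$x), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_x") +
    ggplot2::labs(
      x = "statistic value across iterations", y = "iterations",
      title = sprintf(
        "Degradation draws (p = %.2f, %d iterations)",
        object$config$fraction_p, object$config$n_iterations
      )
    )
}
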