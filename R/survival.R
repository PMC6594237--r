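## Kaplan-Meier median and Cox hazard-ratio estimation contracts.
##
## Thin, contract-enforcing wrappers over the survival package. Input is a
## survival dataset: one row per patient with `time` (days from index,
## positive), `event` (TRUE = death observed) and `arm`. Medians are
## reported in months (30.4375 days/month); the median CI comes from the
## log-log transformed Greenwood pointwise bounds of the survival curve, and
## the Cox model uses the Efron tie correction — integer-day data guarantees
## ties.

validate_survival_data <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("Survival data must be a nonempty data frame.",
      class = "mortsens_error_input"
    )
  }
  needed <- c("time", "event", "arm")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Survival data missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "mortsens_error_input"
    )
  }
  if (any(data$time <= 0)) {
    abort("All survival times must be positive (see build_survival_dataset).",
      class = "mortsens_error_input"
    )
  }
  as_tibble(data)
}

new_estimate <- function(value, ci_lower, ci_upper, n, n_events, subclass) {
  out <- tibble(
    value = value, ci_lower = ci_lower, ci_upper = ci_upper,
    n = as.integer(n), n_events = as.integer(n_events)
  )
  class(out) <- c(subclass, class(out))
  out
}

#' Kaplan-Meier median overall survival
#'
#' Fits the product-limit estimator and reads off the median: the smallest
#' time at which the survival curve falls to 0.5 or below. When the curve
#' never reaches 0.5 the median (and/or its upper bound) is undefined and
#' reported as `NA` — an open interval, not an error. With zero events the
#' estimate is flagged `NA` with a warning rather than raised as an error.
#'
#' @param data Survival data with columns `time` (days), `event`, `arm`.
#' @param conf_level Confidence level for the log-log pointwise bounds
#'   inverted at 0.5 (default 0.95).
#' @return A one-row `km_estimate` tibble: `value`, `ci_lower`, `ci_upper`
#'   (months), `n`, `n_events`.
#' @examples
#' km_median(tibble::tibble(
#'   time = c(1, 2, 3, 4, 5) * 30.4375, event = TRUE, arm = "control"
#' ))
#' @export
km_median <- function(data, conf_level = 0.95) {
  data <- validate_survival_data(data)
  n_events <- sum(data$event)
  if (n_events == 0) {
    warn("No events: Kaplan-Meier median is undefined.")
    return(new_estimate(NA_real_, NA_real_, NA_real_, nrow(data), 0, "km_estimate"))
  }
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data, conf.type = "log-log", conf.int = conf_level
  )
  # smallest time at which the curve falls to 0.5 or below; where the curve
  # sits exactly at 0.5 over a flat segment this takes the segment's start
  # (quantile.survfit would average the boundaries instead)
  at_half <- which(fit$surv <= 0.5 + 1e-9)
  med_days <- if (length(at_half) == 0) NA_real_ else fit$time[at_half[1]]
  q <- quantile(fit, probs = 0.5)
  new_estimate(
    days_to_months(med_days),
    days_to_months(unname(q$lower)),
    days_to_months(unname(q$upper)),
    nrow(data), n_events, "km_estimate"
  )
}

#' Cox proportional-hazards hazard ratio between two arms
#'
#' Estimates the hazard ratio of the non-reference arm versus
#' `reference_arm` by maximum partial likelihood with the Efron tie
#' correction, with a Wald confidence interval. Swapping the reference arm
#' inverts the hazard ratio and its interval; rescaling the time axis leaves
#' it unchanged.
#'
#' @inheritParams km_median
#' @param reference_arm Arm label taken as the denominator (default
#'   `"control"`).
#' @return A one-row `hr_estimate` tibble: `value` (the hazard ratio),
#'   `ci_lower`, `ci_upper`, `n`, `n_events`.
#' @export
cox_hr <- function(data, reference_arm = "control", conf_level = 0.95) {
  data <- validate_survival_data(data)
  arms <- unique(data$arm)
  if (length(arms) != 2) {
    abort(sprintf("Need exactly two arms, found %d.", length(arms)),
      class = "mortsens_error_input"
    )
  }
  if (!reference_arm %in% arms) {
    abort(sprintf("Reference arm '%s' not present in the data.", reference_arm),
      class = "mortsens_error_input"
    )
  }
  events_by_arm <- tapply(data$event, data$arm, sum)
  if (any(events_by_arm == 0)) {
    abort(
      sprintf(
        "No events in arm '%s': the partial likelihood does not converge.",
        names(events_by_arm)[events_by_arm == 0][1]
      ),
      class = "mortsens_error_separation"
    )
  }
  data$arm <- stats::relevel(factor(data$arm), ref = reference_arm)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ arm,
    data = data, ties = "efron"
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  new_estimate(
    exp(beta), exp(beta - z * se), exp(beta + z * se),
    nrow(data), sum(data$event), "hr_estimate"
  )
}

#' Serialise an estimate to JSON
#'
#' Writes `{value, ci_lower, ci_upper, n, n_events}` for a [km_median()] or
#' [cox_hr()] result.
#'
#' @param estimate A `km_estimate` or `hr_estimate` row.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(estimate, path) {
  stopifnot(all(c("value", "ci_lower", "ci_upper", "n", "n_events") %in% names(estimate)))
  jsonlite::write_json(as.list(estimate[1, ]), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read survival datasets as CSV
#'
#' Round-trips the `(time, event, arm)` table fed to the estimators.
#'
#' @param data Survival data.
#' @param path File path.
#' @return `read_survival_csv()` returns the tibble; `write_survival_csv()`
#'   returns `path` invisibly.
#' @export
write_survival_csv <- function(data, path) {
  readr::write_csv(validate_survival_data(data)[, c("time", "event", "arm")], path)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  validate_survival_data(readr::read_csv(
    path,
    col_types = readr::cols(
      time = readr::col_double(),
      event = readr::col_logical(),
      arm = readr::col_character()
    )
  ))
}
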