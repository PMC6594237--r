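## Kaplan-Meier curve plotting.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot Kaplan-Meier curves by arm and death source
#'
#' Draws the product-limit survival curves (time axis in months) for one or
#' more death sources on the same cohort, so the upward shift caused by
#' missed deaths is visible directly.
#'
#' @inheritParams build_survival_dataset
#' @param sources Character vector of death sources to overlay
#'   (default both `"gold"` and `"ehr"`).
#' @return A ggplot object.
#' @export
plot_km_curves <- function(cohort, sources = c("gold", "ehr")) {
  if (!"cell" %in% names(cohort)) {
    cohort <- classify_mortality(cohort)
  }
  curves <- purrr::map(sources, function(src) {
    data <- build_survival_dataset(cohort, src)
    purrr::map(unique(data$arm), function(a) {
      fit <- survival::survfit(
        survival::Surv(time, event) ~ 1,
        data = dplyr::filter(data, .data$arm == a)
      )
      tibble(
        source = src, arm = a,
        time = days_to_months(c(0, fit$time)),
        surv = c(1, fit$surv)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  ggplot2::ggplot(
    curves,
    ggplot2::aes(
      x = .data$time, y = .data$surv,
      colour = .data$arm, linetype = .data$source
    )
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey60", linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "months from index", y = "survival probability",
      colour = "arm", linetype = "death source"
    )
}
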