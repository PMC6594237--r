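# Independent brute-force oracles: the empirical survival function for the
# uncensored KM check and direct 1-D maximisation of the Cox partial
# likelihood (Breslow form; the toy data have no tied death times).

empirical_km_median_days <- function(times) {
  s <- vapply(sort(unique(times)), function(t) mean(times > t), numeric(1))
  sort(unique(times))[which(s <= 0.5)[1]]
}

partial_lik_hr <- function(time, event, x) {
  nll <- function(beta) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; x <- x[ord]
    risk <- exp(beta * x)
    -sum(vapply(which(event == 1), function(i) {
      beta * x[i] - log(sum(risk[time >= time[i]]))
    }, numeric(1)))
  }
  exp(stats::optimize(nll, c(-5, 5), tol = 1e-10)$minimum)
}

surv_tbl <- function(time, event = TRUE, arm = "control") {
  tibble::tibble(time = time, event = rep_len(event, length(time)),
                 arm = rep_len(arm, length(time)))
}

test_that("KM median matches hand-computed product-limit values", {
  # everyone dies at the same time
  est <- km_median(surv_tbl(rep(5 * 30.4375, 8)))
  expect_equal(est$value, 5)
  expect_equal(est$n_events, 8L)

  # S steps 0.8, 0.6, 0.4, ... -> first time S <= 0.5 is the third death
  est <- km_median(surv_tbl(c(1, 2, 3, 4, 5) * 30.4375))
  expect_equal(est$value, 3)

  # S hits exactly 0.5 at the second of four deaths: smallest-t convention
  est <- km_median(surv_tbl(c(1, 2, 3, 4) * 30.4375))
  expect_equal(est$value, 2)
})

test_that("without censoring the KM median equals the empirical one", {
  for (seed in 1:5) {
    times <- withr::with_seed(seed, sample(1:400, 25, replace = TRUE))
    est <- km_median(surv_tbl(times))
    expect_equal(est$value, days_to_months(empirical_km_median_days(times)))
  }
})

test_that("the median ignores where post-last-event censoring falls", {
  events <- surv_tbl(c(30, 60, 90, 120, 150))
  near <- km_median(dplyr::bind_rows(
    events, surv_tbl(c(151, 152, 153), event = FALSE)
  ))
  far <- km_median(dplyr::bind_rows(
    events, surv_tbl(c(500, 900, 1300), event = FALSE)
  ))
  expect_equal(near$value, far$value)
})

test_that("a curve that never reaches half is flagged open, not an error", {
  est <- km_median(dplyr::bind_rows(
    surv_tbl(c(30, 60)),
    surv_tbl(rep(500, 8), event = FALSE)
  ))
  expect_true(is.na(est$value))
  expect_true(is.na(est$ci_upper))
  expect_warning(
    zero <- km_median(surv_tbl(c(10, 20), event = FALSE)),
    "No events"
  )
  expect_true(is.na(zero$value))
  expect_equal(zero$n_events, 0L)
})

test_that("Cox HR agrees with direct partial-likelihood maximisation", {
  toy <- tibble::tibble(
    time = c(2, 4, 6, 8),
    event = c(TRUE, TRUE, TRUE, FALSE),
    arm = c("control", "experimental", "control", "experimental")
  )
  est <- cox_hr(toy, reference_arm = "control")
  oracle <- partial_lik_hr(toy$time, toy$event, as.numeric(toy$arm == "experimental"))
  expect_equal(est$value, oracle, tolerance = 1e-6)

  # a larger random instance, still tie-free
  big <- withr::with_seed(4, tibble::tibble(
    time = sample(seq(1, 4000, by = 7), 60),
    event = sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.8, 0.2)),
    arm = rep(c("control", "experimental"), 30)
  ))
  est <- cox_hr(big)
  oracle <- partial_lik_hr(big$time, big$event, as.numeric(big$arm == "experimental"))
  expect_equal(est$value, oracle, tolerance = 1e-6)
})

test_that("swapping arm labels inverts the HR; rescaling time does nothing", {
  data <- build_survival_dataset(small_cohort(seed = 15), "gold")
  fwd <- cox_hr(data, "control")
  rev <- cox_hr(data, "experimental")
  expect_equal(fwd$value * rev$value, 1, tolerance = 1e-6)
  expect_equal(fwd$ci_lower, 1 / rev$ci_upper, tolerance = 1e-6)

  scaled <- dplyr::mutate(data, time = time / 30.4375)
  expect_equal(cox_hr(scaled, "control")$value, fwd$value, tolerance = 1e-8)
})

test_that("the HR is recovered for exponential arms with a known ratio", {
  data <- withr::with_seed(16, dplyr::bind_rows(
    surv_tbl(rexp(3000, 0.10), arm = "control"),
    surv_tbl(rexp(3000, 0.05), arm = "experimental")
  ))
  est <- cox_hr(data, reference_arm = "control")
  expect_equal(est$value, 0.5, tolerance = 0.1)
  expect_true(est$ci_lower < 0.5 & 0.5 < est$ci_upper)

  null <- withr::with_seed(17, surv_tbl(
    rexp(10000, 0.08),
    arm = rep(c("control", "experimental"), 5000)
  ))
  expect_gt(cox_hr(null)$value, 0.93)
  expect_lt(cox_hr(null)$value, 1.08)
})

test_that("mean log-HR is unbiased over replicates at true HR 0.7", {
  log_hrs <- vapply(1:200, function(i) {
    cohort <- simulate_cohort(cohort_config(
      n_per_arm = 1000, true_hr = 0.7, seed = 3000 + i
    ))
    log(cox_hr(build_survival_dataset(cohort, "gold"))$value)
  }, numeric(1))
  mc_se <- stats::sd(log_hrs) / sqrt(length(log_hrs))
  expect_lt(abs(mean(log_hrs) - log(0.7)), 2 * mc_se)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(
    cox_hr(surv_tbl(c(10, 20), arm = "control")),
    class = "mortsens_error_input"
  )
  one_arm_dead <- dplyr::bind_rows(
    surv_tbl(c(10, 20), arm = "control"),
    surv_tbl(c(30, 40), event = FALSE, arm = "experimental")
  )
  expect_error(cox_hr(one_arm_dead), class = "mortsens_error_separation")
  expect_error(
    cox_hr(build_survival_dataset(small_cohort(1), "gold"), "placebo"),
    class = "mortsens_error_input"
  )
  expect_error(
    km_median(surv_tbl(c(0, 5))),
    class = "mortsens_error_input"
  )
})

test_that("survival datasets round-trip through CSV and JSON", {
  data <- build_survival_dataset(small_cohort(seed = 18, n = 50), "ehr")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(data, csv)
  expect_equal(read_survival_csv(csv), data)

  js <- withr::local_tempfile(fileext = ".json")
  write_estimate(km_median(data), js)
  parsed <- jsonlite::read_json(js)
  expect_named(parsed, c("value", "ci_lower", "ci_upper", "n", "n_events"))
  expect_equal(parsed$n, nrow(data))
})
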