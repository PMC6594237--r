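test_that("degradation reclassifies exactly round(p * |A|) patients to cell C", {
  cohort <- classify_mortality(small_cohort(seed = 9, n = 800))
  before <- tabulate_cells(cohort)
  for (p in c(0.1, 0.2, 0.3, 1)) {
    degraded <- degrade_cohort(cohort, p, seed = 1)
    after <- tabulate_cells(degraded)
    expect_equal(nrow(degraded), nrow(cohort))
    expect_equal(after$a + after$c, before$a + before$c)
    expect_equal(before$a - after$a, round(p * before$a))
    expect_equal(after$b, before$b)
    expect_equal(after$d, before$d)
  }
  # p = 0 is the identity and never mutates its input
  expect_identical(degrade_cohort(cohort, 0, seed = 1), cohort)
  expect_identical(tabulate_cells(cohort), before)
  expect_error(degrade_cohort(cohort, 1.5), class = "mortsens_error_config")
  expect_error(degrade_cohort(cohort, -0.1), class = "mortsens_error_config")
})

test_that("arm restriction degrades only the named arm", {
  cohort <- classify_mortality(small_cohort(seed = 10, n = 800))
  degraded <- degrade_cohort(cohort, 0.3, arms = "control", seed = 2)
  changed <- cohort$cell == "A" & degraded$cell == "C"
  expect_true(all(cohort$arm[changed] == "control"))
  a_control <- sum(cohort$cell == "A" & cohort$arm == "control")
  expect_equal(sum(changed), round(0.3 * a_control))
  exp_rows <- cohort$arm == "experimental"
  expect_identical(degraded[exp_rows, ], cohort[exp_rows, ])
})

test_that("imputed censor dates are uniform between index and gold death", {
  # degrade every captured death so all cell-A patients get a censor draw
  cohort <- classify_mortality(simulate_cohort(
    cohort_config(n_per_arm = 8000, seed = 11)
  ))
  degraded <- degrade_cohort(cohort, 1, seed = 3)
  moved <- cohort$cell == "A"
  censor <- degraded$last_activity_date[moved]
  idx <- degraded$index_date[moved]
  death <- degraded$gold_death_date[moved]
  expect_true(all(censor >= idx))
  expect_true(all(censor < death))
  u <- (censor - idx) / (death - idx)
  expect_gt(length(u), 1e4)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("expected degraded sensitivity matches the closed form", {
  cells <- reference_cell_counts()
  expect_equal(round(100 * expected_degraded_sensitivity(cells, 0.3), 1), 63.4)
  expect_equal(round(100 * expected_degraded_sensitivity(cells, 0.2), 1), 72.5)
  expect_equal(expected_degraded_sensitivity(cells, 1), 0)
  expect_equal(
    expected_degraded_sensitivity(cells, 0),
    capture_metrics(cells)$sensitivity
  )
  expect_error(
    expected_degraded_sensitivity(confusion_counts(0, 1, 0, 5), 0.3),
    class = "mortsens_error_undefined"
  )
  expect_error(
    expected_degraded_sensitivity(cells, 2),
    class = "mortsens_error_config"
  )
})

test_that("degradation studies summarise draws with percentile intervals", {
  cohort <- small_cohort(seed = 12, n = 400)
  cfg <- degradation_config(0.3, n_iterations = 25, seed = 99)

  constant <- run_degradation_study(cohort, cfg, function(x) c(k = 1.5))
  expect_equal(nrow(constant$draws), 25)
  expect_equal(constant$summary$point_estimate, 1.5)
  expect_equal(constant$summary$ci_lower, constant$summary$ci_upper)

  sens <- run_degradation_study(
    cohort, cfg,
    function(x) capture_metrics(tabulate_cells(x))$sensitivity
  )
  g <- glance(sens)
  expect_true(g$ci_lower <= g$point_estimate && g$point_estimate <= g$ci_upper)
  expect_equal(tidy(sens)$iteration, 1:25)

  # reproducible from the master seed, and seed-sensitive
  again <- run_degradation_study(
    cohort, cfg,
    function(x) capture_metrics(tabulate_cells(x))$sensitivity
  )
  expect_identical(glance(again), g)
  other <- run_degradation_study(
    cohort, degradation_config(0.3, 25, seed = 100),
    function(x) km_median(build_survival_dataset(x, "ehr"))$value
  )
  expect_false(identical(other$draws$value, sens$draws$value))
})

test_that("statistic failures surface the iteration index", {
  cohort <- small_cohort(seed = 13, n = 100)
  expect_error(
    run_degradation_study(
      cohort, degradation_config(0.2, 4, seed = 1),
      function(x) stop("boom")
    ),
    "iteration 1",
    class = "mortsens_error_iteration"
  )
})

test_that("the EHR-sourced KM median rises as sensitivity degrades", {
  cohort <- simulate_cohort(cohort_config(n_per_arm = 1500, seed = 21))
  mos <- function(x) km_median(build_survival_dataset(x, "ehr"))$value
  medians <- vapply(c(0, 0.1, 0.2, 0.3), function(p) {
    if (p == 0) {
      return(mos(cohort))
    }
    study <- run_degradation_study(
      cohort, degradation_config(p, n_iterations = 200, seed = 17), mos
    )
    study$summary$point_estimate
  }, numeric(1))
  expect_true(all(diff(medians) > 0))
})

test_that("degradation configs are validated", {
  expect_error(degradation_config(-0.1), class = "mortsens_error_config")
  expect_error(degradation_config(0.3, n_iterations = 0), class = "mortsens_error_config")
})
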