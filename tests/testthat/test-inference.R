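# Bootstrap inference, report shares and the end-to-end driver.

test_that("share-of-first-year percentages match the published arithmetic", {
  inc <- data.table(
    component = rep(c("cost_total", "cost_medication", "cost_non_medication"),
                    each = 2),
    horizon = rep(c(365, 1095), 3),
    estimate = c(247730, 449643, 123998, 212606, 133360, 257232))
  sh <- share_of_first_year(inc)
  expect_identical(sh[component == "cost_total", share_pct], 55)
  expect_identical(sh[component == "cost_medication", share_pct], 58)
  expect_identical(sh[component == "cost_non_medication", share_pct], 52)
  # equal horizons give 100%; zero denominators are undefined
  eq <- data.table(component = "x", horizon = c(365, 1095), estimate = c(5, 5))
  expect_identical(share_of_first_year(eq)$share_pct, 100)
  z <- data.table(component = "x", horizon = c(365, 1095), estimate = c(5, 0))
  expect_true(is.na(share_of_first_year(z)$share_pct))
})

test_that("printed-percentage rounding is half away from zero", {
  expect_identical(kmsacost:::round_half_up(52.5), 53)
  expect_identical(kmsacost:::round_half_up(-52.5), -53)
  expect_identical(kmsacost:::round_half_up(52.4999), 52)
})

test_that("degenerate bootstrap populations have zero spread", {
  y <- rep(500, 40)
  panel <- data.table(patient_id = sprintf("P%03d", 1:40), role = "case",
                      index_date = as.Date("2016-01-01"),
                      matched_set_id = NA_integer_, entered = TRUE)
  panel <- panel[rep(1:40, each = 7)][, period := rep(1:7, 40)]
  panel[, status := "complete"]
  panel[, cost_total := 500]
  persons <- mk_persons(sprintf("P%03d", 1:40))
  bt <- bootstrap_kmsa(panel, NULL, persons, "cost_total", B = 25, seed = 2,
                       covariates = NULL)
  expect_true(all(bt$summary$sd == 0))
  expect_true(all(bt$summary$ci_high - bt$summary$ci_low == 0))
  expect_equal(bt$summary[horizon == 1095, mean], 7 * 500,
               tolerance = 1e-12)
  expect_error(bootstrap_kmsa(panel, NULL, persons, "cost_total", B = 1,
                              covariates = NULL), "B must be")
})

test_that("bootstrap is deterministic given the seed", {
  cfg <- case_only_config(200, seed = 8)
  sim <- simulate_dataset(cfg)
  panel <- build_panel(truth_cohort(sim), sim$claims, sim$persons)
  prof <- flag_comorbidities(truth_cohort(sim), sim$claims)
  b1 <- bootstrap_kmsa(panel, prof, sim$persons, "cost_total", B = 30,
                       seed = 9)
  b2 <- bootstrap_kmsa(panel, prof, sim$persons, "cost_total", B = 30,
                       seed = 9)
  b3 <- bootstrap_kmsa(panel, prof, sim$persons, "cost_total", B = 30,
                       seed = 10)
  expect_equal(b1$summary, b2$summary)
  expect_false(isTRUE(all.equal(b1$summary$mean, b3$summary$mean)))
})

test_that("the bootstrap mean tracks the point estimate on fixed data", {
  cfg <- case_only_config(300, seed = 14)
  sim <- simulate_dataset(cfg)
  panel <- build_panel(truth_cohort(sim), sim$claims, sim$persons)
  prof <- flag_comorbidities(truth_cohort(sim), sim$claims)
  point <- kmsa_estimate(panel, prof, sim$persons, "case", "cost_total",
                         covariates = NULL)[horizon == 1095, estimate]
  bt <- bootstrap_kmsa(panel, prof, sim$persons, "cost_total", B = 600,
                       seed = 5, covariates = NULL)
  bm <- bt$summary[estimand == "case" & horizon == 1095, mean]
  expect_lt(abs(bm / point - 1), 0.02)
})

test_that("bootstrap spread matches the sampling spread of the estimator", {
  # scaled-down re-simulation experiment: the bootstrap SD from one dataset
  # should approximate the empirical SD of the estimator across independent
  # regenerations of the same world
  n <- 400
  point <- vapply(1:150, function(i) {
    cfg <- case_only_config(n, seed = 20000 + i)
    sim <- simulate_dataset(cfg)
    panel <- build_panel(truth_cohort(sim), sim$claims, sim$persons)
    est <- kmsa_estimate(panel, NULL, sim$persons, "case", "cost_total",
                         covariates = NULL)
    est[horizon == 1095, estimate]
  }, numeric(1))
  emp_sd <- sd(point)
  cfg <- case_only_config(n, seed = 20001)
  sim <- simulate_dataset(cfg)
  panel <- build_panel(truth_cohort(sim), sim$claims, sim$persons)
  bt <- bootstrap_kmsa(panel, NULL, sim$persons, "cost_total", B = 200,
                       seed = 31, covariates = NULL)
  boot_sd <- bt$summary[estimand == "case" & horizon == 1095, sd]
  expect_lt(abs(boot_sd / emp_sd - 1), 0.25)
})

test_that("run_study completes end-to-end and reproduces byte-identical artifacts", {
  cfg <- synthetic_config(n_cases = 120, rng_seed = 70)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res <- run_quiet(cfg, seed = 70, out_dir = d1, B = 25)
  expect_true(all(c("table1.csv", "kmsa_estimates.csv", "cohort.csv",
                    "bootstrap_summaries.csv", "manifest.json",
                    "cumulative_costs_by_setting.csv") %in% list.files(d1)))
  # cohort headers reflect the requested 1:10 design
  nn <- attr(res$table1, "n")
  expect_identical(unname(nn["case"]), 120L)
  expect_identical(unname(nn["comparator"]), 1200L)
  # incremental estimates recompute from cohort estimates, shares from
  # incrementals: no hand-entered numbers anywhere in the bundle
  chk <- merge(res$estimates[cohort == "case"],
               res$estimates[cohort == "comparator"],
               by = c("component", "horizon"))
  expect_equal(res$incremental[order(component, horizon), estimate],
               chk[order(component, horizon), estimate.x - estimate.y])
  expect_equal(res$shares,
               share_of_first_year(res$incremental))
  # case costs dominate comparator costs at every horizon
  expect_true(all(res$incremental[component == "cost_total", estimate] > 0))

  res2 <- run_quiet(cfg, seed = 70, out_dir = d2, B = 25)
  expect_identical(readLines(file.path(d1, "kmsa_estimates.csv")),
                   readLines(file.path(d2, "kmsa_estimates.csv")))
  expect_identical(readLines(file.path(d1, "bootstrap_summaries.csv")),
                   readLines(file.path(d2, "bootstrap_summaries.csv")))
})
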