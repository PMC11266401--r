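# Synthetic claims generator: configuration, calibration, determinism.

test_that("configuration validation rejects malformed probability inputs", {
  dem <- default_demographics()
  dem$region_probs["Taipei"] <- 0.5
  expect_error(synthetic_config(n_cases = 10, comparator_pool_size = 100,
                                demographics = dem),
               "sum to 1")
  expect_error(synthetic_config(n_cases = 10, comparator_pool_size = 50),
               "comparator_pool_size")
  expect_error(pexp_hazards(c(0.2, 0.1, 0.3)), "non-decreasing")
  expect_error(pexp_surv(10, c(-0.1, 0, 0, 0)), ">= 0")
})

test_that("demographics hit their calibration targets and degenerate configs collapse", {
  cfg <- case_only_config(100000, seed = 301)
  sim <- generate_persons(cfg)
  p_male <- mean(sim$truth$sex == "male")
  se <- sqrt(0.5907 * (1 - 0.5907) / 100000)
  expect_lt(abs(p_male - 0.5907), 3 * se)
  expect_lt(abs(mean(sim$truth$age_cont) - 60.78), 3 * 14.16 / sqrt(100000) + 0.05)

  dem <- default_demographics()
  dem$p_male <- 1
  dem$age_bands <- data.frame(lower = 50, upper = 51, prob = 1)
  dem$region_probs <- c("Taipei" = 1, "North" = 0, "Central" = 0,
                        "South" = 0, "East" = 0, "Kaohsiung-PingTung" = 0)
  one <- generate_persons(case_only_config(
    50, seed = 1, demographics = dem,
    index_date_window = as.Date(c("2017-01-01", "2017-01-01"))))
  expect_true(all(one$persons$sex == "male"))
  expect_true(all(one$persons$region == "Taipei"))
  expect_equal(length(unique(one$truth$age_years)), 1L)
})

test_that("piecewise-exponential mortality matches its closed form", {
  # constant hazard solved by root-finding reproduces 6-month mortality
  h6 <- uniroot(function(h) 1 - exp(-h * 182.5) - 0.121, c(1e-6, 1),
                tol = 1e-14)$root
  expect_equal(pexp_cdf(182.5, rep(h6, 4)), 0.121, tolerance = 1e-9)

  # default case hazards reproduce all three printed cumulative values
  h <- pexp_hazards(c(0.084, 0.121, 0.188))
  expect_equal(pexp_cdf(c(90, 182, 1095), h), c(0.084, 0.121, 0.188),
               tolerance = 1e-12)

  # two-piece closed form against Monte-Carlo sampling
  h2 <- pexp_hazards(c(0.1, 0.25, 0.25))
  expect_equal(pexp_cdf(182, h2), 1 - exp(-90 * h2[1] - 92 * h2[2]),
               tolerance = 1e-12)
  set.seed(99)
  draws <- pexp_rand(2e5, h2)
  for (tt in c(50, 90, 182, 400)) {
    p <- pexp_cdf(tt, h2)
    expect_lt(abs(mean(draws <= tt) - p), 3 * sqrt(p * (1 - p) / 2e5))
  }

  # null hazards: nobody dies, KM identically one
  cfg <- case_only_config(200, seed = 4, mortality = null_mortality())
  sim <- generate_outcomes(generate_persons(cfg))
  expect_true(all(is.na(sim$persons$death_date)))
  km <- km_fit(survival_input(truth_cohort(sim), sim$persons))
  expect_true(all(km$surv == 1))
})

test_that("expected alive-days integral matches the survival function", {
  h <- pexp_hazards(c(0.084, 0.121, 0.188))
  num <- integrate(function(t) pexp_surv(t, h), 0, 365,
                   subdivisions = 1000L, rel.tol = 1e-10)$value
  expect_equal(pexp_integral(0, 365, h), num, tolerance = 1e-8)
  expect_equal(pexp_integral(100, 100, h), 0)
})

test_that("claims respect follow-up bounds and planted case patterns qualify", {
  cfg <- synthetic_config(n_cases = 150, rng_seed = 11)
  sim <- simulate_dataset(cfg)
  per <- merge(sim$claims, sim$persons, by = "patient_id")
  end <- pmin(per$death_date, per$enroll_end, na.rm = TRUE)
  expect_true(all(per$service_date <= end))
  expect_true(all(per$medication_cost >= 0 & per$non_medication_cost >= 0))
  expect_true(all(per$inpatient_days[per$setting == "inpatient"] >= 1))
  expect_true(all(per$inpatient_days[per$setting != "inpatient"] == 0))

  # cross-module contract: every non-trap case satisfies the
  # case-identification rule, traps never do
  cand <- identify_cases(sim$claims, sim$persons)
  excl <- apply_exclusions(cand, sim$claims, sim$registry_flags)
  expect_setequal(excl$kept$patient_id,
                  sim$truth[role == "case", patient_id])
})

test_that("a null cost process yields an empty but valid claims table", {
  cp <- default_cost_process()
  for (ch in c("case", "comparator")) {
    for (s in names(cp[[ch]])) cp[[ch]][[s]]$annual_counts <- c(0, 0, 0)
  }
  cp$pre_index_multiplier <- list(case = 0, comparator = 0)
  prev <- list(case = setNames(rep(0, 6), names(default_comorbidity_prevalence()$case)),
               comparator = setNames(rep(0, 6), names(default_comorbidity_prevalence()$case)))
  cfg <- case_only_config(20, seed = 2, cost_process = cp,
                          comorbidity_prevalence = prev,
                          plant_patterns = FALSE)
  sim <- simulate_dataset(cfg)
  expect_identical(nrow(sim$claims), 0L)
  # header-only CSV round-trips
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  back <- read_dataset(dir)
  expect_identical(nrow(back$claims), 0L)
  expect_named(back$claims, names(sim$claims))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- synthetic_config(n_cases = 60, rng_seed = 17)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_equal(a$claims, b$claims)
  expect_equal(a$persons, b$persons)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(a, d1); write_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  cfg2 <- synthetic_config(n_cases = 60, rng_seed = 18)
  c2 <- simulate_dataset(cfg2)
  expect_false(identical(a$claims, c2$claims))
})

test_that("datasets round-trip through CSV field-for-field", {
  cfg <- synthetic_config(n_cases = 40, rng_seed = 23)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back$persons), as.data.frame(sim$persons))
  expect_equal(as.data.frame(back$claims), as.data.frame(sim$claims))
  expect_equal(as.data.frame(back$registry_flags),
               as.data.frame(sim$registry_flags))
  expect_identical(back$manifest$config_hash,
                   kmsacost:::config_hash(sim$config))
})

test_that("configurations round-trip through the shipped JSON schema", {
  shipped <- system.file("extdata", "default_synthetic.json",
                         package = "kmsacost")
  cfg <- read_synthetic_config(shipped)
  ref <- synthetic_config()
  expect_identical(kmsacost:::config_hash(cfg), kmsacost:::config_hash(ref))
  expect_identical(generate_persons(cfg)$persons,
                   generate_persons(ref)$persons)
  tmp <- withr::local_tempfile(fileext = ".json")
  custom <- synthetic_config(n_cases = 12, comparator_pool_size = 0,
                             rng_seed = 5, traps = no_traps)
  write_synthetic_config(custom, tmp)
  expect_identical(kmsacost:::config_hash(read_synthetic_config(tmp)),
                   kmsacost:::config_hash(custom))
})

test_that("analytic expectations agree with Monte-Carlo period totals", {
  cfg <- case_only_config(100, seed = 31)
  exp_dt <- expected_costs(cfg, "case")
  tot <- simulate_period_totals(cfg, "case", n = 100000, seed = 77)
  scheme <- period_scheme()
  tot <- merge(tot, as.data.table(scheme)[, .(period, year)], by = "period")
  y1 <- tot[year == 1, .(cost = sum(cost_total), op = sum(n_outpatient),
                         days = sum(hospital_days)), by = patient]
  expect_lt(abs(mean(y1$cost) - exp_dt$cost_total[1]),
            3 * sd(y1$cost) / sqrt(nrow(y1)))
  expect_lt(abs(mean(y1$op) - exp_dt$n_outpatient[1]),
            3 * sd(y1$op) / sqrt(nrow(y1)))
  expect_lt(abs(mean(y1$days) - exp_dt$hospital_days[1]),
            3 * sd(y1$days) / sqrt(nrow(y1)))
  # year-1 targets are the published crude means
  expect_equal(exp_dt$n_outpatient[1], 37.88, tolerance = 1e-9)
  expect_equal(exp_dt$cost_total[1], 294490, tolerance = 1e-6)
  expect_equal(exp_dt$cost_medication[1], 121250, tolerance = 1e-6)
})
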