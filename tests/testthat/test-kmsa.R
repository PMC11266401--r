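# Two-part fits, recycled predictions, survival weighting, incrementals.

# small synthetic panel with one period and given outcomes
mini_panel <- function(y, period = 1L) {
  data.table(patient_id = sprintf("P%03d", seq_along(y)), role = "case",
             index_date = as.Date("2017-01-01"), period = period,
             status = "complete", matched_set_id = NA_integer_,
             entered = TRUE, cost_total = y)
}

test_that("intercept-only two-part fits are exact closed forms", {
  y <- c(rep(0, 6), rep(1000, 4))        # 40% users, mean positive cost 1000
  fit <- fit_two_part(mini_panel(y), profiles = NULL, persons = NULL,
                      covariates = NULL)
  mu <- recycled_predict(fit, matrix(1, 5, 1,
                                     dimnames = list(NULL, "(Intercept)")))
  expect_equal(mu, 0.4 * 1000, tolerance = 1e-12)
  # structural zero
  fit0 <- fit_two_part(mini_panel(rep(0, 8)), NULL, NULL, covariates = NULL)
  expect_true(fit0$structural_zero)
  expect_equal(recycled_predict(fit0, matrix(1, 3, 1)), 0)
  # all positive: part 1 is the constant 1
  fit1 <- fit_two_part(mini_panel(c(10, 20, 30)), NULL, NULL,
                       covariates = NULL)
  expect_equal(fit1$p1_const, 1)
  expect_equal(recycled_predict(fit1, matrix(1, 3, 1)), 20, tolerance = 1e-9)
})

test_that("the fast IRLS engine reproduces stats::glm coefficients", {
  set.seed(881)
  n <- 800
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  eta <- -0.3 + 0.6 * X[, "x1"] - 0.4 * X[, "x2"]
  yb <- rbinom(n, 1, plogis(eta))
  yg <- rgamma(n, shape = 2, scale = exp(0.5 + 0.3 * X[, "x1"]) / 2)
  # both fitters stop on ~1e-8 relative deviance change, so agreement is
  # expected to ~1e-6 relative, far below any statistical resolution
  r1 <- kmsacost:::.irls_fit(X, yb, 0L)
  g1 <- glm.fit(X, yb, family = binomial())
  expect_equal(drop(r1$coef), unname(g1$coefficients), tolerance = 1e-5)
  r2 <- kmsacost:::.irls_fit(X, yg, 1L)
  g2 <- glm.fit(X, yg, family = Gamma(link = "log"))
  expect_equal(drop(r2$coef), unname(g2$coefficients), tolerance = 1e-5)
})

test_that("two-part parameter recovery from a directly simulated panel", {
  set.seed(77)
  n <- 20000
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  alpha <- c(0.4, 0.5, -0.6)
  beta <- c(6.0, 0.25, 0.4)
  use <- rbinom(n, 1, plogis(drop(X %*% alpha)))
  y <- numeric(n)
  pos <- use == 1
  y[pos] <- rgamma(sum(pos), shape = 1.5,
                   scale = exp(drop(X[pos, ] %*% beta)) / 1.5)
  fit <- kmsacost:::twopart_engine(X, y, family2 = "gamma")
  # standard errors from the reference glm fits
  se1 <- sqrt(diag(vcov(glm(use ~ X - 1, family = binomial()))))
  se2 <- sqrt(diag(vcov(glm(y[pos] ~ X[pos, ] - 1,
                            family = Gamma(link = "log")))))
  expect_true(all(abs(fit$part1 - alpha) < 3 * se1))
  expect_true(all(abs(fit$part2 - beta) < 3 * se2))
})

test_that("recycled predictions average per-row two-part products", {
  X <- cbind(`(Intercept)` = 1, x1 = c(0, 1, 2))
  fit <- list(part1 = c(0.2, 0.3), part2 = c(5, -0.1), p1_const = NA_real_,
              structural_zero = FALSE, family2 = "gamma",
              coef_names = colnames(X), notes = character())
  by_hand <- mean(plogis(0.2 + 0.3 * c(0, 1, 2)) *
                    exp(5 - 0.1 * c(0, 1, 2)))
  expect_equal(recycled_predict(fit, X), by_hand, tolerance = 1e-15)
  # null model: everything zero
  fit0 <- list(part1 = c(0, 0), part2 = c(0, 0), p1_const = NA_real_,
               structural_zero = FALSE, family2 = "gamma",
               coef_names = colnames(X), notes = character())
  expect_equal(recycled_predict(fit0, X), 0.5)
  # column mismatch is a contract error
  bad <- cbind(`(Intercept)` = 1, zz = 1:3)
  expect_error(recycled_predict(fit, bad), "do not match")
})

test_that("KMSA weighting reproduces hand computations", {
  sch <- data.table(period = 1:2, start = c(0L, 100L), end = c(100L, 200L),
                    year = c(1L, 1L))
  # ten subjects, one death at t = 50: S(100) = 0.9
  km <- km_fit(data.table(time = c(50, rep(250, 9)), event = c(1, rep(0, 9))))
  est <- kmsa_cumulative(c(100, 200), km, sch, horizons = 200)
  expect_equal(est$estimate, 100 + 0.9 * 200, tolerance = 1e-12)
  # S == 1 everywhere: unweighted sum
  km1 <- km_fit(data.table(time = rep(300, 5), event = rep(0, 5)))
  est1 <- kmsa_cumulative(c(100, 200), km1, sch, horizons = c(100, 200))
  expect_equal(est1$estimate, c(100, 300))
  expect_error(kmsa_cumulative(c(100), km, sch, horizons = 200),
               "one per-period mean")
})

test_that("with no deaths or censoring, KMSA equals the crude cumulative mean", {
  cfg <- case_only_config(500, seed = 3, mortality = null_mortality(),
                          index_date_window = as.Date(c("2016-01-01",
                                                        "2016-01-01")))
  sim <- simulate_dataset(cfg)
  panel <- build_panel(truth_cohort(sim), sim$claims, sim$persons)
  prof <- flag_comorbidities(truth_cohort(sim), sim$claims)
  est <- kmsa_estimate(panel, prof, sim$persons, "case", "cost_total",
                       covariates = NULL)
  crude <- panel[, .(tot = sum(cost_total)), by = patient_id][, mean(tot)]
  expect_equal(est[horizon == 1095, estimate], crude, tolerance = 1e-12)
})

test_that("heavier mortality strictly attenuates the cumulative estimate", {
  sch <- period_scheme()
  mu <- rep(100, 7)
  light <- km_fit(data.table(time = c(100, rep(1200, 49)),
                             event = c(1, rep(0, 49))))
  heavy <- km_fit(data.table(time = c(100, 200, 400, 600, rep(1200, 46)),
                             event = c(1, 1, 1, 1, rep(0, 46))))
  e_light <- kmsa_cumulative(mu, light, sch)[horizon == 1095, estimate]
  e_heavy <- kmsa_cumulative(mu, heavy, sch)[horizon == 1095, estimate]
  expect_lt(e_heavy, e_light)
})

test_that("incremental differences reproduce the published attributable costs", {
  case_est <- data.table(
    component = c("cost_total", "cost_outpatient", "cost_emergency",
                  "cost_inpatient", "cost_medication", "cost_non_medication"),
    horizon = 1095,
    estimate = c(597873, 354666, 17983, 194150, 250430, 367475))
  comp_est <- data.table(
    component = case_est$component, horizon = 1095,
    estimate = c(148230, 95106, 4741, 45943, 37824, 110243))
  inc <- incremental_cost(case_est, comp_est)
  expect_equal(inc[component == "cost_total", estimate], 449643)
  expect_equal(inc[component == "cost_outpatient", estimate], 259560)
  expect_equal(inc[component == "cost_emergency", estimate], 13242)
  expect_equal(inc[component == "cost_inpatient", estimate], 148207)
  # equal inputs difference to zero; mismatched components error
  expect_true(all(incremental_cost(case_est, case_est)$estimate == 0))
  expect_error(incremental_cost(case_est, comp_est[component != "cost_total"]),
               "share components")
})
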