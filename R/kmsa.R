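# Two-part models per observation period, recycled predictions, KMSA
# survival weighting, and incremental (attributable) differences.

#' Covariate design matrix for the two-part models
#'
#' The covariate specification of the cost/HRU regressions: age in years
#' (continuous, or the registry age bands with `age_bands = TRUE`), sex, five
#' region indicator contrasts (Taipei as reference) and the six baseline
#' comorbidity indicators.
#'
#' @param cohort cohort assignments.
#' @param persons person registry.
#' @param profiles comorbidity profiles from [flag_comorbidities()].
#' @param age_bands use the categorical age bands instead of continuous age.
#' @return list with `X` (design matrix, rows in `patient_id` order of the
#'   returned `patient_id` vector) and `patient_id`.
#' @export
covariate_matrix <- function(cohort, persons, profiles, age_bands = FALSE) {
  dt <- merge(as.data.table(cohort), as.data.table(persons), by = "patient_id")
  dt <- merge(dt, as.data.table(profiles), by = "patient_id")
  setorder(dt, patient_id)
  regions <- c("Taipei", "North", "Central", "South", "East",
               "Kaohsiung-PingTung")
  X <- cbind(`(Intercept)` = rep(1, nrow(dt)))
  if (age_bands) {
    band <- cut(as.numeric(dt$index_date - dt$birth_date) / 365.25,
                breaks = c(0, 30, 40, 50, 60, 70, 80, Inf), right = FALSE)
    bm <- stats::model.matrix(~ band)[, -1, drop = FALSE]
    X <- cbind(X, bm)
  } else {
    X <- cbind(X, age = as.numeric(dt$index_date - dt$birth_date) / 365.25)
  }
  X <- cbind(X, male = as.numeric(dt$sex == "male"))
  for (r in regions[-1]) {
    X <- cbind(X, as.numeric(dt$region == r))
    colnames(X)[ncol(X)] <- paste0("region", r)
  }
  for (cat in comorbidity_categories()) {
    X <- cbind(X, as.numeric(dt[[paste0("com_", cat)]]))
    colnames(X)[ncol(X)] <- paste0("com_", cat)
  }
  list(X = X, patient_id = dt$patient_id)
}

# Internal two-part engine on a prepared design matrix.  Returns the
# structure recycled_predict() consumes.  Degenerate configurations are
# resolved exactly:
#   * all-zero outcome            -> structural zero (mu = 0)
#   * all-positive outcome        -> part 1 is the constant probability 1
#   * too few positive rows,      -> intercept-only part 2 (closed form:
#     or part-2 IRLS failure         log link MLE is the log sample mean)
#   * part-1 IRLS failure or      -> intercept-only part 1 (closed form
#     separation blow-up             logit of the use fraction)
twopart_engine <- function(X, y, family2 = c("gamma", "nbinom", "poisson")) {
  family2 <- match.arg(family2)
  p <- ncol(X)
  use <- as.numeric(y > 0)
  fit <- list(part1 = NULL, part2 = NULL, p1_const = NA_real_,
              structural_zero = FALSE, family2 = family2,
              coef_names = colnames(X), notes = character())
  if (all(use == 0)) {
    fit$structural_zero <- TRUE
    return(fit)
  }
  if (all(use == 1)) {
    fit$p1_const <- 1
  } else if (is.null(dim(X)) || p == 1) {
    fit$p1_const <- mean(use)
  } else {
    r <- .irls_fit(X, use, 0L)
    if (r$singular || !r$converged || max(abs(r$coef)) > 30) {
      fit$p1_const <- mean(use)
      fit$notes <- c(fit$notes, "part1 fell back to intercept-only")
    } else {
      fit$part1 <- drop(r$coef)
    }
  }
  ypos <- y[y > 0]
  Xpos <- X[y > 0, , drop = FALSE]
  if (length(ypos) < p + 1 || p == 1) {
    fit$part2 <- c(log(mean(ypos)), rep(0, p - 1))
    if (p > 1) fit$notes <- c(fit$notes, "part2 fell back to intercept-only")
  } else {
    fam_code <- switch(family2, gamma = 1L, poisson = 2L, nbinom = NA_integer_)
    if (family2 == "nbinom") {
      r <- tryCatch(
        suppressWarnings(MASS::glm.nb(ypos ~ Xpos - 1)),
        error = function(e) NULL)
      if (!is.null(r) && all(is.finite(coef(r)))) {
        fit$part2 <- unname(coef(r))
      } else {
        # mean structure of a log-link count model is shared with poisson
        r2 <- .irls_fit(Xpos, ypos, 2L)
        fit$part2 <- if (!r2$singular && r2$converged) drop(r2$coef) else
          c(log(mean(ypos)), rep(0, p - 1))
        fit$notes <- c(fit$notes, "part2 nbinom fell back to poisson mean fit")
      }
    } else {
      r <- .irls_fit(Xpos, ypos, fam_code)
      if (r$singular || !r$converged) {
        fit$part2 <- c(log(mean(ypos)), rep(0, p - 1))
        fit$notes <- c(fit$notes, "part2 fell back to intercept-only")
      } else {
        fit$part2 <- drop(r$coef)
      }
    }
  }
  fit
}

#' Fit a two-part model for one cohort, component and period
#'
#' Part 1 is a maximum-likelihood logistic regression for the probability of
#' any use; part 2 a log-link GLM for the positive amounts (gamma family for
#' costs, negative binomial -- log-link count model -- for counts).  Fitting
#' rows are the panel rows of the cohort and period with status `complete`
#' or `died_within`; rows censored within the period are excluded.
#' Degenerate configurations (all-zero, all-positive, separation, too few
#' positive rows) fall back as described in the returned `notes` rather than
#' failing, so bootstrap replicates never abort.
#'
#' @param panel a [build_panel()] result.
#' @param profiles comorbidity profiles.
#' @param persons person registry.
#' @param cohort `"case"` or `"comparator"`.
#' @param component a panel outcome column, e.g. `"cost_total"`.
#' @param period observation-period number.
#' @param covariates `"default"` for the full covariate specification or
#'   `NULL` for intercept-only fits (closed form).
#' @param family2 part-2 family; defaults to gamma for cost components and
#'   negative binomial for count components.
#' @return object of class `two_part_fit`.
#' @export
fit_two_part <- function(panel, profiles, persons, cohort = "case",
                         component = "cost_total", period = 1L,
                         covariates = "default", family2 = NULL) {
  panel <- as.data.table(panel)
  rows <- panel[role == cohort & period == .env_period &
                  status %in% c("complete", "died_within"),
                env = list(.env_period = period)]
  if (nrow(rows) == 0) stop("no fitting rows for cohort/period", call. = FALSE)
  if (is.null(family2)) {
    family2 <- if (startsWith(component, "cost")) "gamma" else "nbinom"
  }
  if (is.null(covariates)) {
    X <- matrix(1, nrow(rows), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cm <- covariate_matrix(unique(rows[, .(patient_id, index_date)]),
                           persons, profiles)
    X <- cm$X[match(rows$patient_id, cm$patient_id), , drop = FALSE]
  }
  fit <- twopart_engine(X, rows[[component]], family2 = family2)
  fit$cohort <- cohort
  fit$component <- component
  fit$period <- period
  structure(fit, class = "two_part_fit")
}

#' Recycled prediction of the per-period mean
#'
#' Standardises a period's two-part fit over a reference population: the
#' per-period mean is the average over *all* supplied covariate rows
#' (typically the cohort's full baseline membership, regardless of survival)
#' of `P(use) * E[amount | use]`.
#'
#' @param fit a [fit_two_part()] result.
#' @param covariates design matrix with columns matching the fit (or any
#'   matrix for intercept-only fits).
#' @return scalar mean outcome for the period.
#' @export
recycled_predict <- function(fit, covariates) {
  if (fit$structural_zero) return(0)
  p_needed <- length(fit$coef_names)
  if (!is.null(fit$part1) || (!is.null(fit$part2) && any(fit$part2[-1] != 0))) {
    if (ncol(covariates) != p_needed ||
        !identical(colnames(covariates), fit$coef_names)) {
      stop("covariate columns do not match the fitted model", call. = FALSE)
    }
  }
  p1 <- if (!is.null(fit$part1)) {
    plogis(drop(covariates %*% fit$part1))
  } else {
    rep(fit$p1_const, nrow(covariates))
  }
  m2 <- if (length(fit$part2) == ncol(covariates)) {
    exp(drop(covariates %*% fit$part2))
  } else {
    rep(exp(fit$part2[1]), nrow(covariates))
  }
  mean(p1 * m2)
}

# Survival weight "at risk at the start of day s": with day-resolution
# event times a death recorded on a period's first day still contributes
# that period's costs, so it must count as at risk for the period weight.
# Evaluating the step function at s - 0.5 gives P(T >= s); the weight for
# the first period is then exactly 1 even with deaths on day 0.
km_weights <- function(curve, starts) {
  idx <- findInterval(starts - 0.5, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' KMSA cumulative estimate
#'
#' Weights each period's recycled-prediction mean by the Kaplan-Meier
#' probability of being alive at the period start, and sums the weighted
#' means over the periods starting before each horizon:
#' `estimate(h) = sum over p with start_p < h of S(start_p) * mu_p`.
#' Because S is evaluated at period starts, consecutive weights satisfy the
#' conditional-survival chain S(s_p) = S(s_{p-1}) x P(survive the gap).
#'
#' @param mu named numeric vector of per-period means (names = period
#'   numbers), or a list of `two_part_fit`s plus `covariates` to average.
#' @param curve a [km_fit()] of the same cohort.
#' @param scheme the [period_scheme()].
#' @param horizons horizons in days.
#' @param covariates design matrix used when `mu` is a list of fits.
#' @return object of class `kmsa_estimate`: data.table `(horizon, estimate)`
#'   with per-period detail in the `periods` attribute.
#' @export
kmsa_cumulative <- function(mu, curve, scheme = period_scheme(),
                            horizons = c(365, 730, 1095), covariates = NULL) {
  scheme <- as.data.table(scheme)
  if (is.list(mu) && !is.numeric(mu)) {
    if (is.null(covariates)) stop("covariates required with a list of fits",
                                  call. = FALSE)
    mu <- vapply(mu, recycled_predict, numeric(1), covariates = covariates)
  }
  if (length(mu) != nrow(scheme)) {
    stop("need one per-period mean per scheme period", call. = FALSE)
  }
  w <- km_weights(curve, scheme$start)
  weighted <- w * mu
  est <- vapply(horizons, function(h) sum(weighted[scheme$start < h]),
                numeric(1))
  out <- data.table(horizon = horizons, estimate = est)
  setattr(out, "periods", data.table(period = scheme$period,
                                     start = scheme$start, weight = w,
                                     mu = as.numeric(mu),
                                     weighted = weighted))
  setattr(out, "class", c("kmsa_estimate", class(out)))
  out
}

#' Full KMSA estimate for one cohort
#'
#' Convenience wrapper running [fit_two_part()] for every period,
#' [recycled_predict()] over the cohort's full membership and
#' [kmsa_cumulative()], for one or more outcome components.
#'
#' @inheritParams fit_two_part
#' @param components panel outcome columns to estimate.
#' @param curve optional pre-computed [km_fit()]; computed from the panel
#'   cohort and `persons` when omitted.
#' @param scheme the [period_scheme()].
#' @param horizons horizons in days.
#' @return data.table `(cohort, component, horizon, estimate)`.
#' @export
kmsa_estimate <- function(panel, profiles, persons, cohort = "case",
                          components = "cost_total", covariates = "default",
                          curve = NULL, scheme = period_scheme(),
                          horizons = c(365, 730, 1095)) {
  panel <- as.data.table(panel)
  members <- unique(panel[role == cohort, .(patient_id, index_date)])
  if (is.null(curve)) {
    si <- survival_input(unique(panel[role == cohort,
                                      .(patient_id, role, index_date)]),
                         persons)
    curve <- km_fit(si)
  }
  cm <- if (is.null(covariates)) NULL else
    covariate_matrix(members, persons, profiles)
  X <- if (is.null(cm)) matrix(1, nrow(members), 1,
                               dimnames = list(NULL, "(Intercept)")) else cm$X
  out <- lapply(components, function(comp) {
    fits <- lapply(seq_len(nrow(scheme)), function(p) {
      fit_two_part(panel, profiles, persons, cohort, comp, p,
                   covariates = covariates)
    })
    est <- kmsa_cumulative(fits, curve, scheme, horizons, covariates = X)
    data.table(cohort = cohort, component = comp,
               horizon = est$horizon, estimate = est$estimate)
  })
  rbindlist(out)
}

#' Incremental (attributable) differences
#'
#' Case minus comparator estimates per component and horizon.  Components
#' are modelled separately, so component estimates need not sum to the
#' separately modelled total.
#'
#' @param case_est,comp_est data.tables `(component, horizon, estimate)`
#'   from [kmsa_estimate()] (or any table with those columns).
#' @return data.table `(component, horizon, estimate)` of differences.
#' @export
incremental_cost <- function(case_est, comp_est) {
  a <- as.data.table(case_est)[, .(component, horizon, estimate)]
  b <- as.data.table(comp_est)[, .(component, horizon, estimate)]
  if (!identical(a[order(component, horizon), .(component, horizon)],
                 b[order(component, horizon), .(component, horizon)])) {
    stop("estimates do not share components and horizons", call. = FALSE)
  }
  m <- merge(a, b, by = c("component", "horizon"), suffixes = c("_case", "_comp"))
  m[, .(component, horizon, estimate = estimate_case - estimate_comp)]
}
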