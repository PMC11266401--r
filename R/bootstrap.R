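# Bootstrap inference over the full KMSA estimation chain.

# Pack one cohort's panel into aligned matrices for fast resampling:
# row i of every object refers to the same patient.
pack_cohort <- function(panel, profiles, persons, cohort, components,
                        covariates, scheme) {
  members <- unique(panel[role == cohort, .(patient_id, role, index_date)])
  setorder(members, patient_id)
  si <- survival_input(members, persons)
  si <- si[match(members$patient_id, patient_id)]
  X <- if (is.null(covariates)) {
    matrix(1, nrow(members), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cm <- covariate_matrix(members, persons, profiles)
    cm$X[match(members$patient_id, cm$patient_id), , drop = FALSE]
  }
  np <- nrow(scheme)
  eligible <- matrix(FALSE, nrow(members), np)
  Y <- lapply(components, function(comp) matrix(0, nrow(members), np))
  names(Y) <- components
  sub <- panel[role == cohort]
  ridx <- match(sub$patient_id, members$patient_id)
  el <- sub$status %in% c("complete", "died_within")
  eligible[cbind(ridx, sub$period)] <- el
  for (comp in components) {
    Y[[comp]][cbind(ridx, sub$period)] <- sub[[comp]]
  }
  list(n = nrow(members), X = X, time = si$time, event = si$event,
       eligible = eligible, Y = Y, patient_id = members$patient_id,
       set_id = if ("matched_set_id" %in% names(panel))
         unique(panel[role == cohort, .(patient_id, matched_set_id)])[
           match(members$patient_id, patient_id), matched_set_id]
       else rep(NA_integer_, nrow(members)))
}

# One cohort's KMSA cumulatives on a resampled index vector.
kmsa_on_indices <- function(pk, idx, components, scheme, horizons,
                            weights = NULL) {
  w <- if (is.null(weights)) {
    pl_surv_at(pk$time[idx], pk$event[idx], scheme$start - 0.5)
  } else {
    weights
  }
  Xb <- pk$X[idx, , drop = FALSE]
  out <- matrix(NA_real_, length(components), length(horizons),
                dimnames = list(components, NULL))
  for (comp in components) {
    mu <- numeric(nrow(scheme))
    for (p in seq_len(nrow(scheme))) {
      el <- pk$eligible[idx, p]
      y <- pk$Y[[comp]][idx[el], p]
      if (length(y) == 0) { mu[p] <- 0; next }
      fam <- if (startsWith(comp, "cost")) "gamma" else "nbinom"
      fit <- twopart_engine(pk$X[idx[el], , drop = FALSE], y, family2 = fam)
      mu[p] <- recycled_predict(fit, Xb)
    }
    weighted <- w * mu
    out[comp, ] <- vapply(horizons, function(h)
      sum(weighted[scheme$start < h]), numeric(1))
  }
  out
}

#' Bootstrap the KMSA estimates
#'
#' Non-parametric bootstrap over patients: each replicate resamples the case
#' and comparator cohorts independently, with replacement, at their original
#' sizes (all of a patient's periods travel together), then refits the
#' Kaplan-Meier weights and every per-period two-part model, recomputes
#' recycled predictions and cumulative estimates, and takes incremental
#' differences.  Summaries are the replicate mean, SD and 2.5/97.5
#' percentile confidence bounds.  Resampling deliberately breaks matched
#' sets (the cohorts are treated as independent samples);
#' `preserve_sets = TRUE` instead resamples whole matched sets for
#' sensitivity.  `fixed_weights = TRUE` holds the KM weights at their
#' full-sample values instead of refitting them per replicate.
#'
#' The p-value reported for each component is a two-sample t-test on the
#' per-patient observed totals over the full horizon window (cases vs
#' comparators), computed once on the original data.
#'
#' @param panel a [build_panel()] result covering the cohorts.
#' @param profiles comorbidity profiles.
#' @param persons person registry.
#' @param components panel outcome columns to bootstrap.
#' @param B number of replicates (>= 2).
#' @param seed RNG seed.
#' @param covariates `"default"` or `NULL` (intercept-only).
#' @param scheme the [period_scheme()].
#' @param horizons horizons in days.
#' @param fixed_weights hold KM weights fixed across replicates.
#' @param preserve_sets resample matched sets instead of patients.
#' @return object of class `kmsa_bootstrap`: list with `summary` (one row
#'   per estimand: cohort or incremental x component x horizon) and
#'   `replicates` (array `B x estimand`).
#' @export
bootstrap_kmsa <- function(panel, profiles, persons,
                           components = "cost_total", B = 1000L, seed = 1L,
                           covariates = "default",
                           scheme = period_scheme(),
                           horizons = c(365, 730, 1095),
                           fixed_weights = FALSE, preserve_sets = FALSE) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  panel <- as.data.table(panel)
  cohorts <- intersect(c("case", "comparator"), unique(panel$role))
  packs <- lapply(cohorts, function(ch)
    pack_cohort(panel, profiles, persons, ch, components, covariates, scheme))
  names(packs) <- cohorts
  fixed_w <- if (fixed_weights) {
    lapply(packs, function(pk)
      pl_surv_at(pk$time, pk$event, scheme$start - 0.5))
  } else {
    NULL
  }

  set.seed(derive_seed(seed, "bootstrap"))
  # replicate storage: per cohort; incrementals derived afterwards
  reps <- list()
  for (ch in cohorts) {
    reps[[ch]] <- array(NA_real_, c(B, length(components), length(horizons)),
                        dimnames = list(NULL, components, horizons))
  }

  for (b in seq_len(B)) {
    for (ch in cohorts) {
      pk <- packs[[ch]]
      idx <- if (preserve_sets && !all(is.na(pk$set_id))) {
        sets <- unique(pk$set_id)
        drawn <- sample(sets, length(sets), replace = TRUE)
        unlist(lapply(drawn, function(s) which(pk$set_id == s)))
      } else {
        sample.int(pk$n, pk$n, replace = TRUE)
      }
      reps[[ch]][b, , ] <- kmsa_on_indices(
        pk, idx, components, scheme, horizons,
        weights = if (fixed_weights) fixed_w[[ch]] else NULL)
    }
  }

  # observed-total t-tests (original sample, full horizon window)
  pvals <- setNames(rep(NA_real_, length(components)), components)
  if (length(cohorts) == 2) {
    for (comp in components) {
      tc <- rowSums(packs$case$Y[[comp]])
      tm <- rowSums(packs$comparator$Y[[comp]])
      pvals[comp] <- tryCatch(t.test(tc, tm)$p.value, error = function(e) NA_real_)
    }
  }

  summarise <- function(mat, estimand, comp) {
    qs <- apply(mat, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    data.table(estimand = estimand, component = comp,
               horizon = horizons, B = B,
               mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
               ci_low = qs[1, ], ci_high = qs[2, ],
               p_value = pvals[comp])
  }
  out <- list()
  comp_mat <- function(arr, comp) matrix(arr[, comp, ], nrow = B)
  for (ch in cohorts) {
    for (comp in components) {
      out[[paste(ch, comp)]] <- summarise(comp_mat(reps[[ch]], comp), ch, comp)
    }
  }
  if (length(cohorts) == 2) {
    for (comp in components) {
      inc <- comp_mat(reps$case, comp) - comp_mat(reps$comparator, comp)
      out[[paste("incremental", comp)]] <- summarise(inc, "incremental", comp)
    }
  }
  structure(list(summary = rbindlist(out), replicates = reps,
                 components = components, horizons = horizons, B = B),
            class = "kmsa_bootstrap")
}

#' Share of the attributable cost incurred in the first year
#'
#' `100 * (1-year incremental) / (3-year incremental)`, rounded to a whole
#' percent with halves away from zero.  Undefined (zero 3-year denominator)
#' shares are reported as `NA`.
#'
#' @param estimates data.table `(component, horizon, estimate)` of
#'   incremental estimates containing the 365- and 1095-day horizons.
#' @return data.table `(component, share_pct)`.
#' @export
share_of_first_year <- function(estimates) {
  est <- as.data.table(estimates)
  wide <- merge(est[horizon == 365, .(component, y1 = estimate)],
                est[horizon == 1095, .(component, y3 = estimate)],
                by = "component")
  wide[, share_pct := fifelse(y3 == 0, NA_real_,
                              round_half_up(100 * y1 / y3))]
  wide[, .(component, share_pct)]
}
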