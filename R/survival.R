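# Product-limit survival estimation supplying the KMSA period weights.

#' Build survival inputs from a cohort
#'
#' Time is days from the index/reference date to the earlier of death and
#' the administrative data end (`enroll_end`); the event indicator is 1 when
#' the death is observed by the data end.  There is no loss to follow-up:
#' censoring is administrative only.
#'
#' @param cohort cohort assignments (`patient_id`, `role`, `index_date`).
#' @param persons person registry with `death_date` and `enroll_end`.
#' @return data.table `(patient_id, role, time, event)`.
#' @export
survival_input <- function(cohort, persons) {
  dt <- merge(as.data.table(cohort), as.data.table(persons), by = "patient_id")
  dt[, time := as.numeric(pmin(death_date, enroll_end, na.rm = TRUE) - index_date)]
  dt[, event := as.integer(!is.na(death_date) & death_date <= enroll_end)]
  if (any(dt$time < 0)) stop("negative follow-up time", call. = FALSE)
  dt[, .(patient_id, role, time, event)]
}

#' Kaplan-Meier product-limit fit
#'
#' Standard product-limit estimate of S(t) = P(T > t).  Ties between deaths
#' and censorings at the same time are resolved deaths-first (the usual KM
#' convention), so a censored observation at t is still at risk for the
#' death at t.
#'
#' @param inputs data.table with `time` (days, >= 0) and `event` (0/1).
#' @return object of class `km_curve`: data.table with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, plus attributes `n` and `max_time`.
#' @export
km_fit <- function(inputs) {
  inputs <- as.data.table(inputs)
  if (nrow(inputs) == 0) stop("at least one subject required", call. = FALSE)
  if (any(inputs$time < 0)) stop("negative times", call. = FALSE)
  if (!all(inputs$event %in% 0:1)) stop("event must be 0/1", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = inputs)
  out <- data.table(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, surv = sf$surv)
  setattr(out, "n", nrow(inputs))
  setattr(out, "max_time", max(inputs$time))
  setattr(out, "class", c("km_curve", class(out)))
  out
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step-function evaluation of S(t) = P(T > t); deaths at
#' exactly t are included in the drop at t.  Evaluation beyond the last
#' observed time carries the last value forward with a warning.
#'
#' @param curve a [km_fit()] result.
#' @param t_days evaluation times (days, >= 0), vectorised.
#' @return survival probabilities.
#' @export
survival_at <- function(curve, t_days) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t_days < 0)) stop("t_days must be >= 0", call. = FALSE)
  if (any(t_days > attr(curve, "max_time"))) {
    warning("evaluation beyond last observed time; carrying last value forward")
  }
  idx <- findInterval(t_days, curve$time)
  c(1, curve$surv)[idx + 1L]
}

# Minimal product-limit evaluation used in tight loops (bootstrap): survival
# P(T > t) at the requested times, deaths-first at ties.  Kept independent of
# km_fit/survfit so each can cross-check the other.
pl_surv_at <- function(time, event, at) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  n <- length(time)
  dt_times <- unique(time[event == 1])
  if (length(dt_times) == 0) return(rep(1, length(at)))
  # at risk just before t: n - (number with time < t)
  n_risk <- n - findInterval(dt_times - 1e-9, time)
  n_event <- tabulate(match(time[event == 1], dt_times), length(dt_times))
  surv <- cumprod(1 - n_event / n_risk)
  idx <- findInterval(at, dt_times)
  c(1, surv)[idx + 1L]
}
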