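# Patient x observation-period panel: the modeling unit of the partitioned
# cost estimator.

#' Build the patient-by-period panel
#'
#' Aggregates claims into one row per cohort member and observation period.
#' A patient *enters* a period if alive and enrolled on its start day; the
#' row status is `complete` when observed through the period end,
#' `died_within` when death occurs inside the period before the data end
#' (such rows keep their realised partial costs and count as complete
#' observations downstream, because death legitimately terminates cost
#' accrual), `censored_within` when the administrative data end falls inside
#' the period while the patient is alive (partial costs are retained in the
#' panel but the rows are excluded from model fitting), and `not_entered`
#' otherwise (all outcomes zero).  Claims dated outside
#' `[index - 365, index + horizon]` are ignored and counted in the
#' `n_ignored_claims` attribute.
#'
#' @param cohort cohort assignments (`patient_id`, `role`, `index_date`).
#' @param claims claims table.
#' @param persons person registry (`death_date`, `enroll_end`).
#' @param scheme a [period_scheme()].
#' @return data.table with identifiers, `period`, `status`, use counts
#'   (`n_outpatient`, `n_emergency`, `n_admissions`, `hospital_days`) and
#'   cost components (total, per setting, medication/non-medication).
#' @export
build_panel <- function(cohort, claims, persons, scheme = period_scheme()) {
  cohort <- as.data.table(cohort)
  persons <- as.data.table(persons)
  horizon <- max(scheme$end)
  base <- merge(cohort, persons[, .(patient_id, death_date, enroll_end)],
                by = "patient_id")
  base[, death_day := as.numeric(death_date - index_date)]
  base[, censor_day := as.numeric(enroll_end - index_date)]

  # period grid
  if (!"matched_set_id" %in% names(base)) base[, matched_set_id := NA_integer_]
  if (!"role" %in% names(base)) base[, role := "case"]
  grid <- base[, .(patient_id, role, index_date, death_day, censor_day,
                   matched_set_id)]
  grid <- grid[rep(seq_len(nrow(grid)), each = nrow(scheme))]
  grid[, period := rep(scheme$period, length.out = .N)]
  grid[, `:=`(pstart = scheme$start[period], pend = scheme$end[period])]
  grid[, entered := (is.na(death_day) | death_day >= pstart) &
         censor_day >= pstart]
  grid[, status := "not_entered"]
  died <- grid$entered & !is.na(grid$death_day) & grid$death_day < grid$pend &
    grid$death_day <= grid$censor_day
  grid[died, status := "died_within"]
  cens <- grid$entered & grid$status != "died_within" &
    grid$censor_day < grid$pend - 1
  grid[cens, status := "censored_within"]
  grid[entered & status == "not_entered", status := "complete"]

  # aggregate claims into periods
  cl <- merge(as.data.table(claims),
              base[, .(patient_id, index_date)], by = "patient_id",
              allow.cartesian = TRUE)
  cl[, day := as.numeric(service_date - index_date)]
  n_ignored <- sum(cl$day < -365 | cl$day > horizon)
  cl <- cl[day >= 0 & day < horizon]
  cl[, period := findInterval(day, scheme$start)]
  # double precision: annual cohort totals overflow 32-bit integers
  cl[, cost := as.numeric(medication_cost) + as.numeric(non_medication_cost)]
  agg <- cl[, .(
    n_outpatient = sum(setting == "outpatient"),
    n_emergency = sum(setting == "emergency"),
    n_admissions = sum(setting == "inpatient"),
    hospital_days = sum(inpatient_days),
    cost_total = sum(cost),
    cost_outpatient = sum(cost[setting == "outpatient"]),
    cost_inpatient = sum(cost[setting == "inpatient"]),
    cost_emergency = sum(cost[setting == "emergency"]),
    cost_medication = sum(as.numeric(medication_cost)),
    cost_non_medication = sum(as.numeric(non_medication_cost))
  ), by = .(patient_id, period)]

  panel <- merge(grid, agg, by = c("patient_id", "period"), all.x = TRUE)
  value_cols <- c("n_outpatient", "n_emergency", "n_admissions",
                  "hospital_days", "cost_total", "cost_outpatient",
                  "cost_inpatient", "cost_emergency", "cost_medication",
                  "cost_non_medication")
  for (col in value_cols) {
    panel[is.na(get(col)) | status == "not_entered", (col) := 0]
  }
  panel[, c("pstart", "pend", "death_day", "censor_day") := NULL]
  setorder(panel, patient_id, period)
  setattr(panel, "n_ignored_claims", n_ignored)
  panel[]
}

panel_value_cols <- function() {
  c("n_outpatient", "n_emergency", "n_admissions", "hospital_days",
    "cost_total", "cost_outpatient", "cost_inpatient", "cost_emergency",
    "cost_medication", "cost_non_medication")
}

#' Crude annual summaries
#'
#' Raw (survival-unadjusted) per-cohort means of annual HRU and costs: for
#' each follow-up year, the mean over patients who *enter* the year (alive
#' and enrolled at its start) of their observed totals within the year,
#' including partial accrual by patients who die or are censored during the
#' year.  `denominator = "all"` divides by the full cohort instead.
#'
#' @param panel a [build_panel()] result.
#' @param scheme the [period_scheme()] used to build the panel.
#' @param denominator `"entering"` (default) or `"all"`.
#' @return data.table of means by `role` and `year`, with `n_patients`.
#' @export
crude_annual_summary <- function(panel, scheme = period_scheme(),
                                 denominator = c("entering", "all")) {
  denominator <- match.arg(denominator)
  panel <- as.data.table(panel)
  dt <- merge(panel, as.data.table(scheme)[, .(period, year)], by = "period")
  value_cols <- panel_value_cols()
  first_period <- as.data.table(scheme)[, .(period = min(period)), by = year]
  enter <- dt[period %in% first_period$period & status != "not_entered",
              .(patient_id, role, year)]
  totals <- dt[, lapply(.SD, sum), .SDcols = value_cols,
               by = .(patient_id, role, year)]
  if (denominator == "entering") {
    totals <- merge(enter, totals, by = c("patient_id", "role", "year"))
  } else {
    # everyone in the cohort counts in every year's denominator
    totals <- merge(unique(dt[, .(patient_id, role)])[
      , .(year = 1:3), by = .(patient_id, role)], totals,
      by = c("patient_id", "role", "year"), all.x = TRUE)
    for (col in value_cols) totals[is.na(get(col)), (col) := 0]
  }
  out <- totals[, c(list(n_patients = .N), lapply(.SD, mean)),
                .SDcols = value_cols, by = .(role, year)]
  setorder(out, role, year)
  out[]
}

#' Pre-index year summary
#'
#' Per-cohort means of HRU and costs over the baseline window
#' `[index - 365, index - 1]`; a claim on the index date itself is part of
#' follow-up, not baseline.  All cohort members contribute (everyone is
#' alive and enrolled throughout their baseline year by construction of the
#' index date).
#'
#' @param cohort cohort assignments.
#' @param claims claims table.
#' @return data.table of baseline means by `role`.
#' @export
pre_index_summary <- function(cohort, claims) {
  cohort <- as.data.table(cohort)
  cl <- merge(as.data.table(claims), cohort[, .(patient_id, role, index_date)],
              by = "patient_id", allow.cartesian = TRUE)
  cl <- cl[service_date >= index_date - 365L & service_date <= index_date - 1L]
  cl[, cost := as.numeric(medication_cost) + as.numeric(non_medication_cost)]
  agg <- cl[, .(
    n_outpatient = sum(setting == "outpatient"),
    n_emergency = sum(setting == "emergency"),
    n_admissions = sum(setting == "inpatient"),
    hospital_days = sum(inpatient_days),
    cost_total = sum(cost),
    cost_outpatient = sum(cost[setting == "outpatient"]),
    cost_inpatient = sum(cost[setting == "inpatient"]),
    cost_emergency = sum(cost[setting == "emergency"]),
    cost_medication = sum(as.numeric(medication_cost)),
    cost_non_medication = sum(as.numeric(non_medication_cost))
  ), by = .(patient_id, role)]
  full <- merge(cohort[, .(patient_id, role)], agg,
                by = c("patient_id", "role"), all.x = TRUE)
  for (col in panel_value_cols()) full[is.na(get(col)), (col) := 0]
  out <- full[, c(list(n_patients = .N), lapply(.SD, mean)),
              .SDcols = panel_value_cols(), by = role]
  setorder(out, role)
  out[]
}
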