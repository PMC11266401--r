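library(data.table)

# no planted near-case traps (calibration-style worlds)
no_traps <- c(no_biopsy = 0L, single_claim = 0L, short_gap = 0L,
              prior_2015 = 0L, switch = 0L, registry = 0L)

# case-only world: no comparator pool, no traps
case_only_config <- function(n, seed, ...) {
  synthetic_config(n_cases = n, comparator_pool_size = 0L, rng_seed = seed,
                   traps = no_traps, ...)
}

# zero-mortality piecewise configuration
null_mortality <- function() {
  list(breaks = c(90, 182, 1095),
       cum_mortality = list(case = c(0, 0, 0), comparator = c(0, 0, 0)))
}

# cohort table for a generated case-only world (uses generator truth)
truth_cohort <- function(sim, role = "case") {
  sim$truth[sim$truth$role != "pool",
            .(patient_id, role = "case", index_date)]
}

# minimal claims-table constructor for hand-built fixtures
mk_claims <- function(patient_id, service_date, setting = "outpatient",
                      dx_codes = "Z00.0", dx_systems = "icd10",
                      proc_codes = "", medication_cost = 0L,
                      non_medication_cost = 100L, inpatient_days = 0L) {
  data.table(patient_id = patient_id,
             service_date = as.Date(service_date), setting = setting,
             dx_codes = dx_codes, dx_systems = dx_systems,
             proc_codes = proc_codes,
             medication_cost = as.integer(medication_cost),
             non_medication_cost = as.integer(non_medication_cost),
             inpatient_days = as.integer(inpatient_days))
}

mk_persons <- function(patient_id, sex = "male", birth_date = "1955-06-01",
                       region = "Taipei", death_date = NA,
                       enroll_end = "2019-12-31") {
  data.table(patient_id = patient_id, sex = sex,
             birth_date = as.Date(birth_date), region = region,
             death_date = as.Date(death_date),
             enroll_end = as.Date(enroll_end))
}

run_quiet <- function(...) suppressMessages(run_study(...))
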