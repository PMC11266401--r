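#' Synthetic-world configuration
#'
#' `synthetic_config()` assembles the full parameterisation of the synthetic
#' claims world: cohort sizes, the index-date window and administrative data
#' end, demographics, baseline comorbidity prevalences, piecewise-exponential
#' mortality, the per-setting cost/HRU process, multiplicative covariate
#' effects, and the planted "trap" patterns used to exercise the cohort
#' identification rules.  Defaults are calibrated to the published summary
#' statistics of a national matched cohort of newly diagnosed AL amyloidosis
#' patients (645 cases, 1:10 matched): mean age 60.78 y, 59.07% male, six-region
#' residence distribution, case mortality 8.4%/12.1%/18.8% at 3/6/36 months
#' (comparators 0.05%/0.9%/3.7%), year-1 case means of 37.88 outpatient
#' visits, 0.97 ER visits, 1.15 admissions and 12.02 hospital days, and year-1
#' case costs of NT$179,740 (outpatient), NT$108,450 (inpatient), NT$6,300
#' (ER) with a NT$121,250 medication share.  Comparator intensities are
#' back-solved from the published case/comparator ratios (103% more
#' outpatient visits, 177% more ER visits, 4x admissions, 5.5x hospital days,
#' >6x total cost) and are therefore approximate.
#'
#' Generation is a pure function of `(config, rng_seed)`.
#'
#' @param n_cases number of true incident cases to generate.
#' @param comparator_pool_size size of the disease-free comparator pool;
#'   must be at least `10 * n_cases` to support 1:10 exact matching
#'   (the pool is built by cloning cases on the matching keys), or 0 to
#'   generate a case-only world.
#' @param index_date_window date range from which case index dates are drawn
#'   uniformly.
#' @param data_end administrative censoring date (end of data availability).
#' @param rng_seed integer seed; all generation randomness derives from it.
#' @param demographics list with `p_male`, `age_bands` (data.frame with
#'   `lower`, `upper`, `prob`; ages drawn uniformly within a band) and
#'   `region_probs` (named, six regions).
#' @param comorbidity_prevalence list with numeric vectors `case` and
#'   `comparator`, one Bernoulli prevalence per comorbidity category.
#' @param mortality list with `breaks` (hazard change-points, days) and
#'   `cum_mortality` (list `case`/`comparator` of cumulative mortality at the
#'   piece ends).
#' @param cost_process per-cohort, per-setting intensity and cost parameters;
#'   see [default_cost_process()].
#' @param covariate_effects multiplicative effects of age/sex/region/
#'   comorbidity on visit rates and positive-cost means; see
#'   [default_covariate_effects()].  Effects are normalised internally so the
#'   population means stay at their calibration targets.
#' @param traps named integer vector: number of planted near-case patterns per
#'   trap type (`no_biopsy`, `single_claim`, `short_gap`, `prior_2015`,
#'   `switch`, `registry`).
#' @param plant_patterns if `FALSE`, suppress all planted claims (qualifying
#'   index claims, biopsies, comorbidity realisations, trap patterns) and
#'   generate the background cost process only; useful for isolating the cost
#'   model (a null process then yields a truly empty claims table).
#' @param codes diagnosis/procedure code sets used by the generator; see
#'   [default_code_config()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 645L,
                             comparator_pool_size = 10L * n_cases,
                             index_date_window = as.Date(c("2016-01-01", "2018-12-31")),
                             data_end = as.Date("2019-12-31"),
                             rng_seed = 20160101L,
                             demographics = default_demographics(),
                             comorbidity_prevalence = default_comorbidity_prevalence(),
                             mortality = default_mortality(),
                             cost_process = default_cost_process(),
                             covariate_effects = default_covariate_effects(),
                             traps = default_traps(n_cases),
                             codes = default_code_config(),
                             plant_patterns = TRUE) {
  if (n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  if (comparator_pool_size != 0 && comparator_pool_size < 10 * n_cases) {
    stop("comparator_pool_size must be 0 (case-only world) or >= 10 * n_cases",
         call. = FALSE)
  }
  index_date_window <- as.Date(index_date_window)
  data_end <- as.Date(data_end)
  assert_prob_vector(c(demographics$p_male, 1 - demographics$p_male),
                     "demographics$p_male")
  assert_prob_vector(demographics$age_bands$prob, "demographics$age_bands")
  assert_prob_vector(demographics$region_probs, "demographics$region_probs")
  for (cohort in c("case", "comparator")) {
    prev <- comorbidity_prevalence[[cohort]]
    if (any(prev < 0 | prev > 1)) {
      stop("comorbidity prevalences must lie in [0, 1]", call. = FALSE)
    }
    if (any(mortality$cum_mortality[[cohort]] < 0)) {
      stop("cumulative mortality must be >= 0", call. = FALSE)
    }
  }
  structure(list(
    n_cases = as.integer(n_cases),
    comparator_pool_size = as.integer(comparator_pool_size),
    index_date_window = index_date_window,
    data_end = data_end,
    rng_seed = as.integer(rng_seed),
    demographics = demographics,
    comorbidity_prevalence = comorbidity_prevalence,
    mortality = mortality,
    cost_process = cost_process,
    covariate_effects = covariate_effects,
    traps = traps,
    codes = codes,
    plant_patterns = isTRUE(plant_patterns),
    version = "1"
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_demographics <- function() {
  list(
    p_male = 0.5907,
    # Uniform within band; band probabilities follow the published age
    # distribution.  With an open-ended band of [80, 90) the mixture mean is
    # 60.79 y, matching the published 60.78 +/- 14.16 within sampling error.
    age_bands = data.frame(
      lower = c(20, 30, 40, 50, 60, 70, 80),
      upper = c(30, 40, 50, 60, 70, 80, 90),
      prob  = c(0.0295, 0.0450, 0.1240, 0.2667, 0.2744, 0.1736, 0.0868)
    ),
    # Published region split sums to 1.0001; Kaohsiung-PingTung trimmed by
    # 1/10000 so the vector is an exact probability distribution.
    region_probs = c(
      "Taipei" = 0.2620, "North" = 0.2667, "Central" = 0.2186,
      "South" = 0.1132, "East" = 0.0171, "Kaohsiung-PingTung" = 0.1224
    )
  )
}

#' @rdname synthetic_config
#' @export
default_comorbidity_prevalence <- function() {
  list(
    case = c(cardiac = 0.2729, malignancy = 0.2341, renal = 0.2171,
             pulmonary = 0.0651, neuropathy = 0.0248, liver = 0.0233),
    comparator = c(cardiac = 0.1211, malignancy = 0.0443, renal = 0.0380,
                   pulmonary = 0.0026, neuropathy = 0.0051, liver = 0.0009)
  )
}

#' @rdname synthetic_config
#' @export
default_mortality <- function() {
  list(
    breaks = c(90, 182, 1095),
    cum_mortality = list(
      case = c(0.084, 0.121, 0.188),
      comparator = c(0.0005, 0.009, 0.037)
    )
  )
}

#' Default cost/HRU process parameters
#'
#' Per cohort and care setting the generator draws, for every observation
#' period a patient is alive in, a negative-binomial visit count with mean
#' `rate per alive-day x alive-days x covariate multiplier`, and gamma claim
#' costs.  Intensities are year-graded (year 1 / year 2 / year 3 after
#' index).  Values are *annual* targets among patients alive through the
#' year; the generator converts them to per-day rates using the analytic
#' expected alive-days implied by the mortality model, so that published
#' *crude* annual means (which include decedents' partial accrual) are
#' reproduced.
#'
#' Case year-1 values are published figures; year-2/3 case counts and all
#' comparator values are back-solved from published ratios and totals (see
#' the methods vignette).  `unit_cost` is the mean claim cost (per hospital
#' day for the inpatient setting); `med_frac` the deterministic medication
#' share of a claim's cost; `count_size` the negative-binomial size;
#' `cost_shape` the gamma shape of a claim cost (inpatient uses a fixed
#' gamma scale `cost_scale` instead, so per-admission costs stay additive in
#' hospital days); `los` the mean length of stay per admission.
#'
#' @param total_cost_targets named list of annual total-cost targets (NT$)
#'   used to scale year-2/3 unit costs (`case` only; comparator costs are
#'   constant across years).
#' @return nested list consumed by [synthetic_config()].
#' @export
default_cost_process <- function(total_cost_targets = list(case = c(294490, 175400, 152180),
                                                           comparator = 47570)) {
  # year-1 case component costs (published): OP 179,740; IP 108,450; ER 6,300
  case_counts <- list(outpatient = c(37.88, 26, 23),
                      emergency  = c(0.97, 0.55, 0.60),
                      admissions = c(1.15, 0.506, 0.55))
  case_days <- c(12.02, 7.4524, 7.8)           # hospital days per year
  unit_op <- 179740 / 37.88                    # mean cost per OP visit
  unit_er <- 6300 / 0.97
  unit_ip <- 108450 / 12.02                    # mean cost per hospital day
  # scale year-2/3 unit costs so annual totals hit the published totals
  raw_totals <- vapply(1:3, function(y) {
    case_counts$outpatient[y] * unit_op + case_days[y] * unit_ip +
      case_counts$emergency[y] * unit_er
  }, numeric(1))
  alpha <- total_cost_targets$case / raw_totals   # alpha[1] == 1 by design

  comp_counts <- list(outpatient = rep(37.88 / 2.03, 3),
                      emergency  = rep(0.97 / 2.77, 3),
                      admissions = rep(1.15 / 4, 3))
  comp_days <- rep(12.02 / 5.5, 3)
  comp_unit_op <- 1800
  comp_unit_er <- 3000
  comp_unit_ip <- (total_cost_targets$comparator -
                     comp_counts$outpatient[1] * comp_unit_op -
                     comp_counts$emergency[1] * comp_unit_er) / comp_days[1]

  # medication share per setting, chosen so the year-1 case medication total
  # is the published NT$121,250
  med_ip <- 0.30; med_er <- 0.25
  med_op <- (121250 - med_ip * 108450 - med_er * 6300) / 179740

  setting <- function(annual_counts, unit_cost, cost_shape, med_frac,
                      count_size, los = NULL, los_size = NULL,
                      cost_scale = NULL, zero_prob = 0) {
    list(annual_counts = annual_counts, unit_cost = unit_cost,
         cost_shape = cost_shape, med_frac = med_frac,
         count_size = count_size, los = los, los_size = los_size,
         cost_scale = cost_scale, zero_prob = zero_prob)
  }

  list(
    case = list(
      outpatient = setting(case_counts$outpatient, unit_op * alpha, 1.5, med_op, 3),
      emergency  = setting(case_counts$emergency, unit_er * alpha, 1.2, med_er, 0.6),
      inpatient  = setting(case_counts$admissions, unit_ip * alpha, NA, med_ip, 0.8,
                           los = case_days / case_counts$admissions,
                           los_size = 1.2, cost_scale = 6000)
    ),
    comparator = list(
      outpatient = setting(comp_counts$outpatient, rep(comp_unit_op, 3), 1.5, med_op, 3),
      emergency  = setting(comp_counts$emergency, rep(comp_unit_er, 3), 1.2, med_er, 0.6),
      inpatient  = setting(comp_counts$admissions, rep(comp_unit_ip, 3), NA, med_ip, 0.8,
                           los = comp_days / comp_counts$admissions,
                           los_size = 1.2, cost_scale = 6000)
    ),
    # pre-index year: comparators at their steady-state intensity, cases at
    # twice the comparator intensity (prodromal excess use), comparator unit
    # costs for both
    pre_index_multiplier = list(case = 2, comparator = 1)
  )
}

#' @rdname synthetic_config
#' @export
default_covariate_effects <- function() {
  list(
    age_log_slope = 0.006,  # per year of age, on the log rate/cost scale
    age_center = 60.78,
    male = 1.10,
    region = c("Taipei" = 1, "North" = 1, "Central" = 1, "South" = 1,
               "East" = 1, "Kaohsiung-PingTung" = 1),
    comorbidity = c(cardiac = 1.25, malignancy = 1.20, renal = 1.25,
                    pulmonary = 1.15, neuropathy = 1.10, liver = 1.15)
  )
}

#' @rdname synthetic_config
#' @param n_cases number of true cases (trap counts default to 1% each).
#' @export
default_traps <- function(n_cases = 645L) {
  k <- max(1L, as.integer(round(0.01 * n_cases)))
  c(no_biopsy = k, single_claim = k, short_gap = k,
    prior_2015 = k, switch = k, registry = k)
}

#' Code sets used by the synthetic generator
#'
#' Qualifying amyloidosis codes, later-switch codes, the non-AL registry
#' codes, the 2015 ICD-9 exclusion code, a distinguished biopsy procedure
#' code set, and pools of benign background codes guaranteed not to collide
#' with any comorbidity category or amyloidosis code.
#'
#' @export
default_code_config <- function() {
  list(
    qualifying = c("E85.4", "E85.8", "E85.9"),
    switch_codes = c("E85.0", "E85.1", "E85.2", "E83.3"),
    registry_nonal = data.frame(code = c("277.3", "E85.1"),
                                system = c("icd9", "icd10")),
    prior_icd9 = "277.3",
    biopsy_procs = c("BX01", "BX02"),
    benign_icd10 = c("Z00.0", "M54.5", "K21.0", "H52.1", "R51"),
    benign_icd9 = c("V70.0", "724.2", "530.81", "367.1", "784.0")
  )
}

#' Case-identification criteria
#'
#' Parameters of the incident-case rule: a patient qualifies with at least
#' one inpatient claim or at least two outpatient claims carrying a
#' qualifying code in any diagnosis position, with some qualifying
#' outpatient pair at least `outpatient_gap_days` apart; the index date is
#' the first claim bearing a qualifying code; a biopsy procedure claim is
#' required within `biopsy_window` days of the index (closed interval).
#' Exclusions: any 2015 claim with the legacy ICD-9 amyloidosis code, any
#' post-index switch to another amyloidosis code, or a non-AL flag in the
#' catastrophic-illness registry.
#'
#' `E83.3` is implemented in the switch list as published; it can be
#' replaced (e.g. by `E85.3`) through this constructor.
#'
#' @param qualifying_codes ICD-10 codes identifying the disease.
#' @param min_inpatient,min_outpatient claim-count thresholds.
#' @param outpatient_gap_days minimum gap between some pair of qualifying
#'   outpatient claims (evaluated as last minus first `>=` gap).
#' @param biopsy_window `c(lower, upper)` day offsets around the index date.
#' @param biopsy_procs procedure codes accepted as biopsy confirmation.
#' @param exclusion_year calendar year scanned for the legacy ICD-9 code.
#' @param exclusion_codes_2015 legacy ICD-9 code(s).
#' @param switch_codes post-index amyloidosis codes triggering exclusion.
#' @param registry_nonal_codes data.frame (`code`, `system`) of registry
#'   flags triggering exclusion.
#' @return object of class `case_criteria`.
#' @export
case_criteria <- function(qualifying_codes = c("E85.4", "E85.8", "E85.9"),
                          min_inpatient = 1L,
                          min_outpatient = 2L,
                          outpatient_gap_days = 30L,
                          biopsy_window = c(-365L, 182L),
                          biopsy_procs = c("BX01", "BX02"),
                          exclusion_year = 2015L,
                          exclusion_codes_2015 = "277.3",
                          switch_codes = c("E85.0", "E85.1", "E85.2", "E83.3"),
                          registry_nonal_codes = data.frame(
                            code = c("277.3", "E85.1"),
                            system = c("icd9", "icd10"))) {
  stopifnot(length(qualifying_codes) >= 1, biopsy_window[1] <= biopsy_window[2])
  structure(list(
    qualifying_codes = qualifying_codes,
    min_inpatient = as.integer(min_inpatient),
    min_outpatient = as.integer(min_outpatient),
    outpatient_gap_days = as.integer(outpatient_gap_days),
    biopsy_window = as.integer(biopsy_window),
    biopsy_procs = biopsy_procs,
    exclusion_year = as.integer(exclusion_year),
    exclusion_codes_2015 = exclusion_codes_2015,
    switch_codes = switch_codes,
    registry_nonal_codes = registry_nonal_codes
  ), class = "case_criteria")
}

#' Default comorbidity code lists
#'
#' Illustrative ICD-9/ICD-10 code lists for the six comorbidity categories,
#' matched by prefix in any diagnosis position.  The original study's
#' supplementary lists are not publicly available; these defaults are
#' clinically plausible stand-ins and are fully replaceable.
#'
#' @return named list of lists with `icd9` and `icd10` character vectors,
#'   one per category.
#' @export
default_codelists <- function() {
  list(
    cardiac    = list(icd10 = c("I50", "I42"), icd9 = c("428", "425")),
    liver      = list(icd10 = c("K70", "K71", "K72", "K73", "K74"), icd9 = "571"),
    renal      = list(icd10 = c("N17", "N18"), icd9 = c("584", "585")),
    pulmonary  = list(icd10 = c("J44", "J84"), icd9 = c("496", "515")),
    neuropathy = list(icd10 = c("G62", "G63"), icd9 = c("356", "357")),
    malignancy = list(icd10 = c("C34", "C50", "C90"), icd9 = c("162", "174", "203"))
  )
}

comorbidity_categories <- function() {
  c("cardiac", "liver", "renal", "pulmonary", "neuropathy", "malignancy")
}

#' Observation-period scheme
#'
#' Follow-up is partitioned into seven modeling periods: four year-1
#' quarters of 91/91/91/92 days (so the year boundary lands exactly on day
#' 365), two year-2 half-years, and one year-3 period, covering `[0, 1095)`
#' days from index with no gaps.  This is the collapsed version of a
#' 12-quarter partition, which remains available via
#' `period_scheme("quarterly")` for sensitivity analyses.
#'
#' @param type `"collapsed"` (default, 7 periods) or `"quarterly"`
#'   (12 periods of 91/92 days).
#' @return object of class `period_scheme`: data.table with `period`,
#'   `start`, `end` (half-open `[start, end)` day intervals) and `year`.
#' @export
period_scheme <- function(type = c("collapsed", "quarterly")) {
  type <- match.arg(type)
  if (type == "collapsed") {
    start <- c(0, 91, 182, 273, 365, 548, 730)
    end   <- c(91, 182, 273, 365, 548, 730, 1095)
  } else {
    q <- c(91, 91, 91, 92)
    widths <- rep(q, 3)
    end <- cumsum(widths)
    start <- end - widths
  }
  out <- data.table(
    period = seq_along(start),
    start = as.integer(start),
    end = as.integer(end)
  )
  out[, year := findInterval(start, c(0, 365, 730)) ]
  structure(out, class = c("period_scheme", class(out)))
}

#' Read and write configurations as JSON
#'
#' Configurations serialise to plain JSON (dates as ISO-8601 strings) so a
#' study is reproducible from a text artefact.  `read_synthetic_config()`
#' validates through [synthetic_config()].
#'
#' @param config a `synthetic_config` object.
#' @param path file path.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$index_date_window <- format(x$index_date_window)
  x$data_end <- format(x$data_end)
  # named vectors must become JSON objects, or their names are lost
  x$demographics$region_probs <- as.list(x$demographics$region_probs)
  x$comorbidity_prevalence <- lapply(x$comorbidity_prevalence, as.list)
  x$covariate_effects$region <- as.list(x$covariate_effects$region)
  x$covariate_effects$comorbidity <- as.list(x$covariate_effects$comorbidity)
  x$traps <- as.list(x$traps)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$codes$registry_nonal <- as.data.frame(x$codes$registry_nonal)
  x$traps <- unlist(x$traps)
  # JSON has no NULL-vs-empty distinction: restore absent setting fields
  x$cost_process[c("case", "comparator")] <-
    lapply(x$cost_process[c("case", "comparator")], function(cohort) {
      lapply(cohort, function(s) {
        for (k in names(s)) {
          if (length(s[[k]]) == 0) {
            s[k] <- if (k == "cost_shape") list(NA) else list(NULL)
          }
        }
        s
      })
    })
  synthetic_config(
    n_cases = x$n_cases,
    comparator_pool_size = x$comparator_pool_size,
    index_date_window = as.Date(x$index_date_window),
    data_end = as.Date(x$data_end),
    rng_seed = x$rng_seed,
    demographics = list(
      p_male = x$demographics$p_male,
      age_bands = as.data.frame(x$demographics$age_bands),
      region_probs = unlist(x$demographics$region_probs)
    ),
    comorbidity_prevalence = lapply(x$comorbidity_prevalence, unlist),
    mortality = list(breaks = x$mortality$breaks,
                     cum_mortality = lapply(x$mortality$cum_mortality, unlist)),
    cost_process = x$cost_process,
    covariate_effects = lapply(x$covariate_effects, unlist),
    traps = x$traps,
    codes = x$codes,
    plant_patterns = x$plant_patterns %||% TRUE
  )
}

# Config fingerprint recorded in dataset manifests.
config_hash <- function(config) {
  x <- unclass(config)
  x$index_date_window <- format(x$index_date_window)
  x$data_end <- format(x$data_end)
  h <- fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
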