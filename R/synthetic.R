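#' Generate a synthetic person registry
#'
#' Draws the case cohort-to-be, the planted "trap" patients (near-cases that
#' the identification rules must reject), and a disease-free comparator pool.
#' Pool members are demographic clones of cases on the matching keys (sex,
#' region, birth date), cycled so every case is guaranteed at least
#' `comparator_pool_size / n_cases` exact twins; this makes full 1:10 exact
#' matching feasible by construction.  Case index dates are drawn uniformly
#' from the configured window; a pool member inherits its donor case's index
#' date as the clock origin for mortality and cost generation (it becomes the
#' reference date if the member is later matched).
#'
#' Latent per-person quantities needed by downstream generation steps —
#' planted comorbidity indicators, continuous age, covariate multipliers and
#' the planted role/index date — are kept in a `truth` table alongside the
#' plain person registry.  The truth table is generator metadata: the
#' analysis pipeline never reads it, but tests use it as ground truth.
#'
#' @param config a [synthetic_config()].
#' @return object of class `claims_sim`: list with `persons`, `truth` and the
#'   `config`; later stages add `claims` and `registry_flags`.
#' @export
generate_persons <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$rng_seed, "persons"))
  dem <- config$demographics
  n_case <- config$n_cases
  n_trap <- sum(config$traps)
  n_pool <- config$comparator_pool_size

  draw_demo <- function(n) {
    bands <- dem$age_bands
    b <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$prob)
    age <- runif(n, bands$lower[b], bands$upper[b])
    data.table(
      sex = ifelse(runif(n) < dem$p_male, "male", "female"),
      age = age,
      region = sample(names(dem$region_probs), n, replace = TRUE,
                      prob = dem$region_probs)
    )
  }

  window <- config$index_date_window
  n_cl <- n_case + n_trap   # case-like persons
  demo <- draw_demo(n_cl)
  index_date <- window[1] +
    floor(runif(n_cl) * (as.numeric(window[2] - window[1]) + 1))
  birth_date <- index_date - as.integer(round(demo$age * 365.25))

  roles <- c(rep("case", n_case),
             rep(paste0("trap_", names(config$traps)), config$traps))

  case_like <- data.table(
    role = roles, sex = demo$sex, region = demo$region,
    birth_date = birth_date, index_date = index_date,
    case_ref = NA_character_
  )

  if (n_pool > 0) {
    # clone pool members from true cases, cycling so each case gets at least
    # floor(n_pool / n_case) dedicated exact twins on the matching keys;
    # cases occupy rows 1..n_case, so the donor's patient_id is known
    donor <- rep(seq_len(n_case), length.out = n_pool)
    pool <- data.table(
      role = "pool",
      sex = case_like$sex[donor], region = case_like$region[donor],
      birth_date = case_like$birth_date[donor],
      index_date = case_like$index_date[donor],
      case_ref = sprintf("P%06d", donor)
    )
  } else {
    pool <- NULL
  }

  truth <- rbindlist(list(case_like, pool), fill = TRUE)
  truth[, patient_id := sprintf("P%06d", .I)]
  truth[, age_years := completed_years(birth_date, index_date)]
  truth[, age_cont := as.numeric(index_date - birth_date) / 365.25]

  # planted comorbidity indicators (independent Bernoulli per category)
  prev <- config$comorbidity_prevalence
  for (cat in comorbidity_categories()) {
    p <- ifelse(truth$role == "pool", prev$comparator[[cat]], prev$case[[cat]])
    truth[, paste0("com_", cat) := runif(.N) < p]
  }

  # covariate multipliers on visit rates (g_count) and positive-cost means
  # (g_cost), normalised analytically so population-level calibration
  # targets are preserved: E[g_count] = 1 and E[g_count * g_cost] = 1
  eff <- config$covariate_effects
  g_raw <- exp(eff$age_log_slope * (truth$age_cont - eff$age_center)) *
    ifelse(truth$sex == "male", eff$male, 1) *
    eff$region[truth$region]
  for (cat in comorbidity_categories()) {
    g_raw <- g_raw * ifelse(truth[[paste0("com_", cat)]],
                            eff$comorbidity[[cat]], 1)
  }
  for (cohort in c("case", "comparator")) {
    mom <- covariate_moments(config, cohort)
    rows <- if (cohort == "case") truth$role != "pool" else truth$role == "pool"
    truth[rows, g_count := g_raw[rows] / mom$m1]
    truth[rows, g_cost := g_raw[rows] * mom$m1 / mom$m2]
  }

  persons <- truth[, .(patient_id, sex, birth_date, region,
                       death_date = as.Date(NA), enroll_end = config$data_end)]
  setkey(persons, patient_id)
  structure(list(persons = persons, truth = truth, config = config),
            class = "claims_sim")
}

# Analytic first and second moments of the raw covariate multiplier under a
# cohort's covariate distribution (independent components by construction).
covariate_moments <- function(config, cohort) {
  eff <- config$covariate_effects
  dem <- config$demographics
  prev <- config$comorbidity_prevalence[[cohort]]
  mom_k <- function(k) {
    g <- k * eff$age_log_slope
    bands <- dem$age_bands
    age_m <- if (abs(g) < 1e-12) 1 else {
      sum(bands$prob * (exp(g * bands$upper) - exp(g * bands$lower)) /
            (g * (bands$upper - bands$lower))) * exp(-g * eff$age_center)
    }
    sex_m <- dem$p_male * eff$male^k + (1 - dem$p_male)
    reg_m <- sum(dem$region_probs * eff$region[names(dem$region_probs)]^k)
    com_m <- prod(1 - prev + prev * eff$comorbidity[names(prev)]^k)
    age_m * sex_m * reg_m * com_m
  }
  list(m1 = mom_k(1), m2 = mom_k(2))
}

mortality_hazards <- function(config, cohort) {
  pexp_hazards(config$mortality$cum_mortality[[cohort]],
               config$mortality$breaks)
}

#' Generate death outcomes
#'
#' Draws piecewise-exponential survival times from the index/reference date:
#' cases (and traps) from the case hazards, pool members from the comparator
#' hazards.  Trap survival is truncated below 400 days so every planted claim
#' pattern can be realised in full.  The recorded `death_date` is the index
#' date plus the completed day of death; deaths after the administrative data
#' end are still recorded (the analysis truncates at `enroll_end` itself).
#' Survival times are independent of the administrative censoring times given
#' covariates, the independence the KMSA estimator assumes.
#'
#' @param sim a `claims_sim` from [generate_persons()].
#' @param config configuration; defaults to the one stored in `sim`.
#' @return `sim` with `death_date` filled in and `death_time` (continuous
#'   days) added to the truth table.
#' @export
generate_outcomes <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "claims_sim"))
  set.seed(derive_seed(config$rng_seed, "outcomes"))
  truth <- sim$truth
  h_case <- mortality_hazards(config, "case")
  h_comp <- mortality_hazards(config, "comparator")
  brk <- config$mortality$breaks

  truth[, death_time := NA_real_]
  is_case <- truth$role == "case"
  is_trap <- startsWith(truth$role, "trap_")
  truth[is_case, death_time := pexp_rand(sum(is_case), h_case, brk)]
  truth[is_trap, death_time := pexp_rand(sum(is_trap), h_case, brk, lower = 400)]
  truth[role == "pool",
        death_time := pexp_rand(sum(truth$role == "pool"), h_comp, brk)]

  truth[, death_date := fifelse(is.finite(death_time),
                                index_date + floor(death_time), as.Date(NA))]
  sim$persons[truth, death_date := i.death_date, on = "patient_id"]
  sim$truth <- truth
  sim
}

# Per-day background visit rates by cohort, setting and follow-up year,
# calibrated so expected *crude* annual means (partial accrual by decedents
# included) hit the configured annual targets.  Case year-1 admissions are
# reduced by the planted index admission.
setting_rates <- function(config, cohort) {
  h <- mortality_hazards(config, cohort)
  brk <- config$mortality$breaks
  S <- function(t) pexp_surv(t, h, brk)
  # expected alive-days in year y per patient alive at the year start
  expo <- vapply(1:3, function(y) {
    a <- c(0, 365, 730)[y]; b <- c(365, 730, 1095)[y]
    pexp_integral(a, b, h, brk) / S(a)
  }, numeric(1))
  proc <- config$cost_process[[cohort]]
  rates <- lapply(names(proc), function(s) {
    planted <- if (cohort == "case" && s == "inpatient") c(1, 0, 0) else c(0, 0, 0)
    pmax(0, unlist(proc[[s]]$annual_counts) - planted) / expo
  })
  names(rates) <- names(proc)
  rates
}

# Draw per-patient, per-period, per-setting counts and aggregate amounts.
# `exposure` is alive-and-enrolled days in the period; the compound gamma
# totals are distributionally identical to summing per-claim gamma draws.
draw_period_block <- function(n, setting_cfg, rate_day, unit_cost, exposure,
                              g_count, g_cost, planted_adm = NULL) {
  size <- setting_cfg$count_size
  mu <- rate_day * exposure * g_count
  count <- integer(n)
  pos <- mu > 0
  count[pos] <- rnbinom(sum(pos), size = size, mu = mu[pos])
  zp <- setting_cfg$zero_prob %||% 0
  if (zp > 0) count[runif(n) < zp] <- 0L
  out <- data.table(count = count)
  if (!is.null(setting_cfg$los)) {
    los_mu <- setting_cfg$los_mu   # mean LOS for this year, injected by caller
    days <- integer(n); cost <- numeric(n)
    k <- count > 0
    if (any(k)) {
      days[k] <- count[k] + rnbinom(sum(k), size = setting_cfg$los_size * count[k],
                                    mu = (los_mu - 1) * count[k])
      theta <- setting_cfg$cost_scale
      cost[k] <- rgamma(sum(k), shape = unit_cost * days[k] * g_cost[k] / theta,
                        scale = theta)
    }
    if (!is.null(planted_adm)) {
      # index admission: one extra admission at day 0, cost without the
      # covariate multiplier so the calibration target is exact
      pl_days <- 1L + rnbinom(n, size = setting_cfg$los_size, mu = los_mu - 1)
      theta <- setting_cfg$cost_scale
      pl_cost <- rgamma(n, shape = unit_cost * pl_days / theta, scale = theta)
      count <- count + 1L; days <- days + pl_days; cost <- cost + pl_cost
      out[, count := count]
    }
    out[, `:=`(days = days, cost = cost)]
  } else {
    shape <- setting_cfg$cost_shape
    cost <- numeric(n)
    k <- count > 0
    if (any(k)) {
      cost[k] <- rgamma(sum(k), shape = shape * count[k],
                        scale = unit_cost * g_cost[k] / shape)
    }
    out[, `:=`(days = 0L, cost = cost)]
  }
  out
}

#' Generate the claims table
#'
#' Expands the configured cost process into one row per claim.  Every true
#' case receives a qualifying inpatient claim on the index date (with the
#' qualifying amyloidosis code in the primary position, or the secondary
#' position for 30% of cases) carrying a biopsy procedure code; trap patients
#' receive their designated broken pattern instead.  Planted baseline claims
#' realise each comorbidity flag as two outpatient claims with a category
#' code in the baseline year.  Background claims carry benign codes only
#' (ICD-9 before 2016, ICD-10 after), so planted truth stays exact.  No claim
#' is dated after `min(death_date, data_end)`.
#'
#' @param sim a `claims_sim` with outcomes generated.
#' @param config configuration; defaults to the one stored in `sim`.
#' @return `sim` with `claims` and `registry_flags` tables added.
#' @export
generate_claims <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "claims_sim"), !is.null(sim$truth$death_time))
  set.seed(derive_seed(config$rng_seed, "claims"))
  truth <- sim$truth
  scheme <- period_scheme()
  codes <- config$codes
  pieces <- list()

  for (cohort in c("case", "comparator")) {
    rows <- if (cohort == "case") !truth$role %in% "pool" else truth$role == "pool"
    tt <- truth[rows]
    if (nrow(tt) == 0) next
    n <- nrow(tt)
    censor_day <- as.numeric(config$data_end - tt$index_date)
    rates <- setting_rates(config, cohort)
    proc <- config$cost_process[[cohort]]

    # follow-up periods
    for (p in seq_len(nrow(scheme))) {
      sp <- scheme$start[p]; ep <- scheme$end[p]; yr <- scheme$year[p]
      exposure <- pmax(0, pmin(tt$death_time, censor_day + 1, ep) - sp)
      last_day <- pmin(ep - 1, floor(tt$death_time), censor_day)
      for (s in names(proc)) {
        cfg_s <- proc[[s]]
        cfg_s$los_mu <- if (!is.null(cfg_s$los)) unlist(cfg_s$los)[yr] else NULL
        blk <- draw_period_block(
          n, cfg_s, rates[[s]][yr], unlist(cfg_s$unit_cost)[yr], exposure,
          tt$g_count, tt$g_cost, planted_adm = NULL
        )
        pieces[[length(pieces) + 1L]] <-
          expand_claims(tt, blk, s, cfg_s, sp, last_day, codes)
      }
    }

    # pre-index year: steady background use in [-365, -1]
    mult <- config$cost_process$pre_index_multiplier[[cohort]]
    comp_proc <- config$cost_process$comparator
    for (s in names(comp_proc)) {
      cfg_s <- comp_proc[[s]]
      cfg_s$los_mu <- if (!is.null(cfg_s$los)) unlist(cfg_s$los)[1] else NULL
      rate_day <- mult * unlist(cfg_s$annual_counts)[1] / 365
      blk <- draw_period_block(n, cfg_s, rate_day, unlist(cfg_s$unit_cost)[1],
                               rep(365, n), tt$g_count, tt$g_cost)
      pieces[[length(pieces) + 1L]] <-
        expand_claims(tt, blk, s, cfg_s, -365L, rep(-1, n), codes)
    }
  }

  # planted comorbidity claims: two baseline outpatient claims per flag
  codelists <- default_codelists()
  op_case <- config$cost_process$case$outpatient
  if (!isTRUE(config$plant_patterns)) {
    claims <- rbindlist(pieces, use.names = TRUE)
    if (is.null(claims) || nrow(claims) == 0) claims <- empty_claims()
    sim$claims <- claims[order(patient_id, service_date, setting)]
    sim$registry_flags <- data.table(patient_id = character(),
                                     flag_code = character(),
                                     flag_system = character())
    return(sim)
  }
  for (cat in comorbidity_categories()) {
    flagged <- truth[truth[[paste0("com_", cat)]] == TRUE]
    if (nrow(flagged) == 0) next
    for (rep_i in 1:2) {
      day <- -1L - floor(runif(nrow(flagged)) * 365)
      date <- flagged$index_date + day
      icd10 <- format(date, "%Y") >= "2016"
      code <- ifelse(icd10, codelists[[cat]]$icd10[1], codelists[[cat]]$icd9[1])
      cost <- round(rgamma(nrow(flagged), shape = op_case$cost_shape,
                           scale = 1800 / op_case$cost_shape))
      med <- round(op_case$med_frac * cost)
      pieces[[length(pieces) + 1L]] <- data.table(
        patient_id = flagged$patient_id, service_date = date,
        setting = "outpatient", dx_codes = code,
        dx_systems = ifelse(icd10, "icd10", "icd9"), proc_codes = "",
        medication_cost = as.integer(med),
        non_medication_cost = as.integer(cost - med), inpatient_days = 0L
      )
    }
  }

  pieces[[length(pieces) + 1L]] <- planted_index_claims(truth, config)
  claims <- rbindlist(pieces, use.names = TRUE)
  if (is.null(claims) || nrow(claims) == 0) claims <- empty_claims()
  claims <- claims[order(patient_id, service_date, setting)]

  regs <- truth[role == "trap_registry"]
  reg_codes <- codes$registry_nonal
  sim$registry_flags <- if (nrow(regs) > 0) {
    pick <- 1 + (seq_len(nrow(regs)) %% nrow(reg_codes))
    data.table(patient_id = regs$patient_id,
               flag_code = reg_codes$code[pick],
               flag_system = reg_codes$system[pick])
  } else {
    data.table(patient_id = character(), flag_code = character(),
               flag_system = character())
  }
  sim$claims <- claims
  sim
}

empty_claims <- function() {
  data.table(patient_id = character(), service_date = as.Date(character()),
             setting = character(), dx_codes = character(),
             dx_systems = character(), proc_codes = character(),
             medication_cost = integer(), non_medication_cost = integer(),
             inpatient_days = integer())
}

# Expand a per-patient block of (count, days, cost) into claim rows with
# dates uniform over the patient's alive days in the period.
expand_claims <- function(tt, blk, s, cfg_s, sp, last_day, codes) {
  idx <- rep(seq_len(nrow(tt)), blk$count)
  if (length(idx) == 0) return(NULL)
  n_claims <- blk$count[idx]
  day <- sp + floor(runif(length(idx)) * (last_day[idx] - sp + 1))
  date <- tt$index_date[idx] + day
  # split each patient's aggregate cost (and days) evenly across their claims
  # in the block; totals, not per-claim allocation, are what is calibrated
  cost <- blk$cost[idx] / n_claims
  days <- if (s == "inpatient") pmax(1L, round(blk$days[idx] / n_claims)) else 0L
  cost_i <- round(cost)
  med <- round(cfg_s$med_frac * cost_i)
  icd10 <- format(date, "%Y") >= "2016"
  code <- ifelse(icd10,
                 sample(codes$benign_icd10, length(idx), replace = TRUE),
                 sample(codes$benign_icd9, length(idx), replace = TRUE))
  data.table(
    patient_id = tt$patient_id[idx], service_date = date, setting = s,
    dx_codes = code, dx_systems = ifelse(icd10, "icd10", "icd9"),
    proc_codes = "", medication_cost = as.integer(med),
    non_medication_cost = as.integer(cost_i - med),
    inpatient_days = as.integer(days)
  )
}

# Planted qualifying/trap claim patterns at and around the index date.
planted_index_claims <- function(truth, config) {
  codes <- config$codes
  tt <- truth[role != "pool"]
  if (nrow(tt) == 0) return(NULL)
  n <- nrow(tt)
  ip <- config$cost_process$case$inpatient
  los_mu <- unlist(ip$los)[1]
  unit_ip <- unlist(ip$unit_cost)[1]
  op <- config$cost_process$case$outpatient
  unit_op <- unlist(op$unit_cost)[1]

  qual <- sample(codes$qualifying, n, replace = TRUE)
  secondary <- runif(n) < 0.30
  benign <- sample(codes$benign_icd10, n, replace = TRUE)
  dx <- ifelse(secondary, paste(benign, qual, sep = "|"), qual)
  dxsys <- ifelse(secondary, "icd10|icd10", "icd10")
  biopsy <- sample(codes$biopsy_procs, n, replace = TRUE)

  mk_op <- function(rows, day, dx, dxsys, proc) {
    m <- length(rows)
    cost <- round(rgamma(m, shape = op$cost_shape, scale = unit_op / op$cost_shape))
    med <- round(op$med_frac * cost)
    data.table(patient_id = tt$patient_id[rows],
               service_date = tt$index_date[rows] + day,
               setting = "outpatient", dx_codes = dx, dx_systems = dxsys,
               proc_codes = proc, medication_cost = as.integer(med),
               non_medication_cost = as.integer(cost - med), inpatient_days = 0L)
  }
  mk_ip <- function(rows, proc) {
    m <- length(rows)
    days <- 1L + rnbinom(m, size = ip$los_size, mu = los_mu - 1)
    cost <- round(rgamma(m, shape = unit_ip * days / ip$cost_scale,
                         scale = ip$cost_scale))
    med <- round(ip$med_frac * cost)
    data.table(patient_id = tt$patient_id[rows],
               service_date = tt$index_date[rows],
               setting = "inpatient", dx_codes = dx[rows],
               dx_systems = dxsys[rows], proc_codes = proc,
               medication_cost = as.integer(med),
               non_medication_cost = as.integer(cost - med),
               inpatient_days = as.integer(days))
  }

  pieces <- list()
  # qualifying inpatient claim with biopsy for cases and the traps whose
  # defect lies elsewhere
  full_pattern <- which(tt$role %in% c("case", "trap_prior_2015",
                                       "trap_switch", "trap_registry"))
  if (length(full_pattern)) {
    pieces$full <- mk_ip(full_pattern, biopsy[full_pattern])
  }
  nb <- which(tt$role == "trap_no_biopsy")
  if (length(nb)) pieces$no_biopsy <- mk_ip(nb, "")

  sc <- which(tt$role == "trap_single_claim")
  if (length(sc)) {
    pieces$single <- mk_op(sc, 0L, qual[sc], "icd10", biopsy[sc])
  }
  sg <- which(tt$role == "trap_short_gap")
  if (length(sg)) {
    pieces$sg1 <- mk_op(sg, 0L, qual[sg], "icd10", biopsy[sg])
    pieces$sg2 <- mk_op(sg, 29L, qual[sg], "icd10", "")
  }
  p15 <- which(tt$role == "trap_prior_2015")
  if (length(p15)) {
    m <- length(p15)
    date <- as.Date("2015-01-01") + floor(runif(m) * 365)
    cost <- round(rgamma(m, shape = op$cost_shape, scale = 1800 / op$cost_shape))
    med <- round(op$med_frac * cost)
    pieces$p15 <- data.table(
      patient_id = tt$patient_id[p15], service_date = date,
      setting = "outpatient", dx_codes = config$codes$prior_icd9,
      dx_systems = "icd9", proc_codes = "",
      medication_cost = as.integer(med),
      non_medication_cost = as.integer(cost - med), inpatient_days = 0L)
  }
  sw <- which(tt$role == "trap_switch")
  if (length(sw)) {
    swc <- sample(codes$switch_codes, length(sw), replace = TRUE)
    pieces$sw <- mk_op(sw, 60L, swc, "icd10", "")
  }
  rbindlist(pieces, use.names = TRUE)
}

#' Simulate uncensored per-period totals (Monte-Carlo truth)
#'
#' Draws patient-by-period aggregate outcomes directly from the configured
#' cost process without expanding to claim rows, using the exact compound
#' distributions the claim-level generator induces (a sum of iid gamma claim
#' costs is gamma with summed shape).  With `censoring = FALSE` follow-up is
#' truncated by death only, which makes this the Monte-Carlo oracle for the
#' true mean cumulative cost that the censoring-adjusted estimator targets.
#'
#' @param config a [synthetic_config()].
#' @param cohort `"case"` or `"comparator"`.
#' @param n number of simulated patients.
#' @param seed RNG seed.
#' @param censoring if `TRUE`, apply administrative censoring from index
#'   dates drawn as in the full generator.
#' @return data.table with one row per patient x period: `count` per setting,
#'   `hospital_days`, and cost components.
#' @export
simulate_period_totals <- function(config, cohort = "case", n = 1e5,
                                   seed = config$rng_seed,
                                   censoring = FALSE) {
  set.seed(derive_seed(seed, paste0("totals_", cohort)))
  scheme <- period_scheme()
  dem <- config$demographics
  prev <- config$comorbidity_prevalence[[cohort]]
  eff <- config$covariate_effects

  bands <- dem$age_bands
  b <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$prob)
  age <- runif(n, bands$lower[b], bands$upper[b])
  male <- runif(n) < dem$p_male
  region <- sample(names(dem$region_probs), n, replace = TRUE,
                   prob = dem$region_probs)
  g <- exp(eff$age_log_slope * (age - eff$age_center)) *
    ifelse(male, eff$male, 1) * eff$region[region]
  for (cat in comorbidity_categories()) {
    g <- g * ifelse(runif(n) < prev[[cat]], eff$comorbidity[[cat]], 1)
  }
  mom <- covariate_moments(config, cohort)
  g_count <- g / mom$m1
  g_cost <- g * mom$m1 / mom$m2

  h <- mortality_hazards(config, cohort)
  brk <- config$mortality$breaks
  death_time <- pexp_rand(n, h, brk)
  censor_day <- if (censoring) {
    window <- config$index_date_window
    idx <- window[1] + floor(runif(n) * (as.numeric(window[2] - window[1]) + 1))
    as.numeric(config$data_end - idx)
  } else {
    rep(Inf, n)
  }

  rates <- setting_rates(config, cohort)
  proc <- config$cost_process[[cohort]]
  out <- vector("list", nrow(scheme))
  for (p in seq_len(nrow(scheme))) {
    sp <- scheme$start[p]; ep <- scheme$end[p]; yr <- scheme$year[p]
    exposure <- pmax(0, pmin(death_time, censor_day + 1, ep) - sp)
    row <- data.table(patient = seq_len(n), period = p)
    total <- med <- numeric(n)
    for (s in names(proc)) {
      cfg_s <- proc[[s]]
      cfg_s$los_mu <- if (!is.null(cfg_s$los)) unlist(cfg_s$los)[yr] else NULL
      blk <- draw_period_block(
        n, cfg_s, rates[[s]][yr], unlist(cfg_s$unit_cost)[yr], exposure,
        g_count, g_cost,
        planted_adm = if (cohort == "case" && s == "inpatient" && p == 1) TRUE else NULL
      )
      row[, paste0("n_", s) := blk$count]
      if (s == "inpatient") row[, hospital_days := blk$days]
      row[, paste0("cost_", s) := blk$cost]
      total <- total + blk$cost
      med <- med + cfg_s$med_frac * blk$cost
    }
    row[, `:=`(cost_total = total, cost_medication = med,
               cost_non_medication = total - med)]
    out[[p]] <- row
  }
  rbindlist(out)
}

#' Analytic expected crude annual outcomes
#'
#' Closed-form expectations of the crude annual means the generator is
#' calibrated to: per-setting visit counts, hospital days and cost
#' components, among patients alive at the start of each follow-up year
#' (death truncation included, administrative censoring excluded).  Used as
#' the analytic side of generator-validation tests.
#'
#' @param config a [synthetic_config()].
#' @param cohort `"case"` or `"comparator"`.
#' @return data.table with one row per year and expected outcome columns.
#' @export
expected_costs <- function(config, cohort = "case") {
  h <- mortality_hazards(config, cohort)
  brk <- config$mortality$breaks
  rates <- setting_rates(config, cohort)
  proc <- config$cost_process[[cohort]]
  mom <- covariate_moments(config, cohort)
  e_gcost <- mom$m1^2 / mom$m2   # E[g_cost]; E[g_count] = 1, E[g_count g_cost] = 1
  out <- list()
  for (y in 1:3) {
    a <- c(0, 365, 730)[y]; b <- c(365, 730, 1095)[y]
    expo <- pexp_integral(a, b, h, brk) / pexp_surv(a, h, brk)
    row <- list(year = y)
    total <- med <- 0
    for (s in names(proc)) {
      cfg_s <- proc[[s]]
      planted <- if (cohort == "case" && s == "inpatient" && y == 1) 1 else 0
      cnt <- planted + rates[[s]][y] * expo
      unit <- unlist(cfg_s$unit_cost)[y]
      if (s == "inpatient") {
        los <- unlist(cfg_s$los)[y]
        days <- cnt * los
        cost <- planted * los * unit + (cnt - planted) * los * unit
        row$hospital_days <- days
      } else {
        cost <- cnt * unit
      }
      row[[paste0("n_", s)]] <- cnt
      row[[paste0("cost_", s)]] <- cost
      total <- total + cost
      med <- med + cfg_s$med_frac * cost
    }
    row$cost_total <- total
    row$cost_medication <- med
    row$cost_non_medication <- total - med
    out[[y]] <- as.data.table(row)
  }
  rbindlist(out)
}

#' One-call synthetic dataset
#'
#' Runs [generate_persons()], [generate_outcomes()] and [generate_claims()].
#'
#' @inheritParams generate_persons
#' @export
simulate_dataset <- function(config) {
  generate_claims(generate_outcomes(generate_persons(config)))
}

#' Write and read a synthetic dataset
#'
#' Writes `persons.csv`, `claims.csv`, `registry_flags.csv`, `truth.csv` and
#' a `manifest.json` recording the seed and a config fingerprint.  Dates are
#' ISO-8601; costs integer NT$.  `read_dataset()` restores the tables
#' field-for-field.
#'
#' @param sim a `claims_sim` with claims generated.
#' @param path output directory (created if missing).
#' @export
write_dataset <- function(sim, path) {
  stopifnot(inherits(sim, "claims_sim"), !is.null(sim$claims))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path,
                              call. = FALSE)
  fwrite(sim$persons, file.path(path, "persons.csv"))
  fwrite(sim$claims, file.path(path, "claims.csv"))
  fwrite(sim$registry_flags, file.path(path, "registry_flags.csv"))
  truth_out <- copy(sim$truth)
  fwrite(truth_out, file.path(path, "truth.csv"))
  manifest <- list(
    package = "kmsacost",
    created = "see manifest_hash",   # no timestamp: outputs must be byte-identical
    rng_seed = sim$config$rng_seed,
    config_hash = config_hash(sim$config),
    n_persons = nrow(sim$persons),
    n_claims = nrow(sim$claims)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  as_date_safe <- function(x) {
    if (inherits(x, "Date")) return(x)
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    as.Date(x)
  }
  persons <- fread(file.path(path, "persons.csv"),
                   colClasses = list(character = "patient_id"))
  for (col in c("birth_date", "death_date", "enroll_end")) {
    persons[, (col) := as_date_safe(get(col))]
  }
  claims <- fread(file.path(path, "claims.csv"),
                  colClasses = list(character = c("patient_id", "dx_codes",
                                                  "dx_systems", "proc_codes")))
  claims[, service_date := as_date_safe(service_date)]
  claims[, proc_codes := fifelse(is.na(proc_codes), "", proc_codes)]
  regf <- fread(file.path(path, "registry_flags.csv"),
                colClasses = "character")
  truth <- NULL
  if (file.exists(file.path(path, "truth.csv"))) {
    truth <- fread(file.path(path, "truth.csv"),
                   colClasses = list(character = c("patient_id", "case_ref")))
    for (col in c("birth_date", "index_date", "death_date")) {
      truth[, (col) := as_date_safe(get(col))]
    }
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  setkey(persons, patient_id)
  structure(list(persons = persons, claims = claims, registry_flags = regf,
                 truth = truth, manifest = manifest),
            class = "claims_sim")
}
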