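# Cohort construction: case identification, exclusions, exact matching.

# Long (patient, date, setting, position, system, code) view of the packed
# dx columns; position 1 is the primary diagnosis.
explode_dx <- function(claims) {
  codes <- strsplit(claims$dx_codes, "|", fixed = TRUE)
  systems <- strsplit(claims$dx_systems, "|", fixed = TRUE)
  nn <- lengths(codes)
  idx <- rep(seq_len(nrow(claims)), nn)
  data.table(
    claim_row = idx,
    patient_id = claims$patient_id[idx],
    service_date = claims$service_date[idx],
    setting = claims$setting[idx],
    pos = sequence(nn),
    code = unlist(codes),
    system = unlist(systems)
  )
}

has_proc <- function(claims, proc_set) {
  x <- claims$proc_codes
  ok <- x %in% proc_set                      # fast path: single code per claim
  multi <- which(!ok & grepl("|", x, fixed = TRUE))
  if (length(multi)) {
    ok[multi] <- vapply(strsplit(x[multi], "|", fixed = TRUE),
                        function(p) any(p %in% proc_set), logical(1))
  }
  ok
}

#' Identify newly diagnosed cases from claims
#'
#' A patient qualifies if they have at least one inpatient claim carrying a
#' qualifying diagnosis code in any position, or at least two qualifying
#' outpatient claims with some pair at least `outpatient_gap_days` apart
#' (evaluated as last minus first qualifying outpatient date, which is
#' equivalent to the existence of one such pair).  The index date is the
#' date of the first claim bearing a qualifying code in any setting, even if
#' the qualifying pattern only completes later.  Patients without a biopsy
#' procedure claim inside the closed window `index + biopsy_window` days are
#' dropped; they are reported in the `dropped_no_biopsy` attribute.
#'
#' @param claims claims table (see [simulate_dataset()] for the column
#'   contract).
#' @param persons person registry; every claim must reference a registered
#'   patient.
#' @param criteria a [case_criteria()].
#' @return data.table `(patient_id, index_date)`, keyed by patient, with
#'   attribute `dropped_no_biopsy`.
#' @export
identify_cases <- function(claims, persons, criteria = case_criteria()) {
  claims <- as.data.table(claims)
  unknown <- setdiff(claims$patient_id, persons$patient_id)
  if (length(unknown) > 0) {
    stop("claims reference unknown patients: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  dx <- explode_dx(claims)
  qual <- dx[code %in% criteria$qualifying_codes]
  if (nrow(qual) == 0) {
    out <- data.table(patient_id = character(), index_date = as.Date(character()))
    setattr(out, "dropped_no_biopsy", character())
    return(out)
  }
  by_pat <- qual[, {
    ip <- sum(setting == "inpatient")
    op_dates <- sort(unique(service_date[setting == "outpatient"]))
    op_ok <- length(op_dates) >= criteria$min_outpatient &&
      as.numeric(max(op_dates) - min(op_dates)) >= criteria$outpatient_gap_days
    list(qualifies = ip >= criteria$min_inpatient || op_ok,
         index_date = min(service_date))
  }, by = patient_id]
  cand <- by_pat[qualifies == TRUE, .(patient_id, index_date)]

  # biopsy confirmation within the window around the index date
  bio <- claims[has_proc(claims, biopsy_codes(criteria)),
                .(patient_id, service_date)]
  cand <- merge(cand, bio, by = "patient_id", all.x = TRUE, allow.cartesian = TRUE)
  cand[, ok := !is.na(service_date) &
         service_date >= index_date + criteria$biopsy_window[1] &
         service_date <= index_date + criteria$biopsy_window[2]]
  keep <- cand[, .(ok = any(ok)), by = .(patient_id, index_date)]
  dropped <- keep[ok == FALSE, patient_id]
  out <- keep[ok == TRUE, .(patient_id, index_date)]
  setkey(out, patient_id)
  setattr(out, "dropped_no_biopsy", dropped)
  out[]
}

# The biopsy procedure code set travels with the criteria so users can
# swap fee-schedule codes; defaults mirror the synthetic generator.
biopsy_codes <- function(criteria) {
  criteria$biopsy_procs %||% default_code_config()$biopsy_procs
}

#' Apply case exclusions
#'
#' Removes candidates with (in this fixed order, first matching rule wins):
#' any claim in the exclusion year carrying the legacy ICD-9 amyloidosis
#' code (`prior_2015`); a non-AL amyloidosis flag in the catastrophic-illness
#' registry (`registry`); or any post-index claim bearing a switch code
#' (`switch`).
#'
#' @param candidates output of [identify_cases()].
#' @param claims claims table.
#' @param registry_flags data.table `(patient_id, flag_code, flag_system)`;
#'   may be empty or `NULL`.
#' @param criteria a [case_criteria()].
#' @return list with `kept` (patient_id, index_date) and `excluded`
#'   (patient_id, reason).
#' @export
apply_exclusions <- function(candidates, claims, registry_flags = NULL,
                             criteria = case_criteria()) {
  candidates <- as.data.table(candidates)
  dx <- explode_dx(claims[patient_id %in% candidates$patient_id])
  dx[, year := as.integer(format(service_date, "%Y"))]

  prior <- unique(dx[system == "icd9" & code %in% criteria$exclusion_codes_2015 &
                       year == criteria$exclusion_year, patient_id])
  reg <- character()
  if (!is.null(registry_flags) && nrow(registry_flags) > 0) {
    rf <- as.data.table(registry_flags)
    nonal <- criteria$registry_nonal_codes
    hit <- rf[paste(flag_code, flag_system) %in% paste(nonal$code, nonal$system)]
    reg <- unique(hit$patient_id)
  }
  dxi <- merge(dx, candidates, by = "patient_id")
  sw <- unique(dxi[service_date > index_date & code %in% criteria$switch_codes,
                   patient_id])

  excluded <- rbindlist(list(
    data.table(patient_id = prior, reason = "prior_2015"),
    data.table(patient_id = setdiff(reg, prior), reason = "registry"),
    data.table(patient_id = setdiff(sw, c(prior, reg)), reason = "switch")
  ))
  kept <- candidates[!patient_id %in% excluded$patient_id]
  setkey(kept, patient_id)
  list(kept = kept[], excluded = excluded[order(patient_id)])
}

#' Match comparators 1:k on sex, region and age
#'
#' Each case is matched to `ratio` comparators drawn uniformly without
#' replacement from pool members agreeing exactly on sex, region and age in
#' completed years at the case's index date and alive on that date (the
#' source population at the reference date); a comparator serves at most one
#' case.  Cases are processed in ascending index-date then patient-id order
#' on a canonically sorted pool, so the assignment is deterministic given
#' the seed and invariant to input row order.  When the greedy draw leaves a
#' later case short even though a full assignment exists (earlier cases with
#' coincident keys may have consumed its twins), an augmenting-path repair
#' reassigns members between key-compatible cases; the insufficient-pool
#' error is raised only when no valid assignment exists at all.  Matched
#' comparators inherit the case's index date as their reference date.
#'
#' @param cases data.table `(patient_id, index_date)`.
#' @param pool character vector of comparator-pool patient ids (persons with
#'   no qualifying disease claim in the data window).
#' @param persons person registry.
#' @param ratio comparators per case.
#' @param seed RNG seed for the uniform draws.
#' @param age_widen if `TRUE`, fall back to age +/- 1 year when a case has
#'   fewer than `ratio` exact-age twins (off by default).
#' @return data.table of cohort assignments: `patient_id`, `role`
#'   (case/comparator), `index_date`, `matched_set_id`.
#' @export
match_comparators <- function(cases, pool, persons, ratio = 10L, seed = 1L,
                              age_widen = FALSE) {
  cases <- as.data.table(cases)
  setorder(cases, index_date, patient_id)
  per <- as.data.table(persons)[patient_id %in% pool,
                                .(patient_id, sex, region, birth_date,
                                  death_date)]
  setorder(per, patient_id)
  case_per <- as.data.table(persons)[cases, on = "patient_id",
                                     .(patient_id, sex, region, birth_date,
                                       index_date = i.index_date)]
  setorder(case_per, index_date, patient_id)
  n_case <- nrow(case_per)

  # eligibility is case-specific (age in completed years at the case's own
  # index date), computed lazily within (sex, region) strata
  strata <- split(seq_len(nrow(per)), paste(per$sex, per$region))
  elig_cache <- vector("list", n_case)
  eligible <- function(i) {
    if (!is.null(elig_cache[[i]])) return(elig_cache[[i]])
    cs <- case_per[i]
    rows <- strata[[paste(cs$sex, cs$region)]]
    if (is.null(rows)) rows <- integer()
    age_i <- completed_years(cs$birth_date, cs$index_date)
    ages <- completed_years(per$birth_date[rows], cs$index_date)
    alive <- is.na(per$death_date[rows]) | per$death_date[rows] > cs$index_date
    hit <- rows[ages == age_i & alive]
    if (length(hit) < ratio && age_widen) {
      hit <- rows[abs(ages - age_i) <= 1L & alive]
    }
    elig_cache[[i]] <<- hit
    hit
  }

  set.seed(derive_seed(seed, "matching"))
  assigned_to <- integer(nrow(per))   # 0 = unused, else case number

  # a greedy uniform draw can starve a later case even though a full
  # matching exists (every case has dedicated exact twins); repair by
  # augmenting-path search over cases, which finds a reassignment whenever
  # one exists and errors otherwise
  augment <- function(i) {
    parent_case <- integer(n_case)      # BFS tree over cases
    parent_member <- integer(n_case)    # member linking child to parent
    visited <- logical(n_case); visited[i] <- TRUE
    queue <- i
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      el <- eligible(j)
      free <- el[assigned_to[el] == 0L]
      if (length(free) > 0) {
        m <- free[1]
        # walk back to the starving case, shifting one member per link
        while (j != i) {
          assigned_to[m] <<- j
          m <- parent_member[j]
          j <- parent_case[j]
        }
        assigned_to[m] <<- i
        return(TRUE)
      }
      holders <- unique(assigned_to[el])
      for (h in holders) {
        if (!visited[h]) {
          visited[h] <- TRUE
          parent_case[h] <- j
          parent_member[h] <- el[assigned_to[el] == h][1]
          queue <- c(queue, h)
        }
      }
    }
    FALSE
  }

  for (i in seq_len(n_case)) {
    el <- eligible(i)
    free <- el[assigned_to[el] == 0L]
    take <- min(ratio, length(free))
    if (take > 0) {
      pick <- if (length(free) == take) free else sample(free, take)
      assigned_to[pick] <- i
    }
    short <- ratio - take
    while (short > 0) {
      if (!augment(i)) {
        stop(sprintf(
          "insufficient comparator pool for case %s (need %d exact matches)",
          case_per$patient_id[i], ratio), call. = FALSE)
      }
      short <- short - 1L
    }
  }

  out <- vector("list", 2L * n_case)
  for (i in seq_len(n_case)) {
    members <- per$patient_id[assigned_to == i]
    out[[2 * i - 1L]] <- data.table(patient_id = case_per$patient_id[i],
                                    role = "case",
                                    index_date = case_per$index_date[i],
                                    matched_set_id = i)
    out[[2 * i]] <- data.table(patient_id = sort(members), role = "comparator",
                               index_date = case_per$index_date[i],
                               matched_set_id = i)
  }
  rbindlist(out)
}

#' Build the full matched cohort from raw tables
#'
#' Convenience wrapper: identifies cases, applies exclusions, forms the
#' comparator pool (registered persons with no qualifying-code claim at all
#' and no candidate status), and matches `ratio` comparators per case.
#'
#' @inheritParams identify_cases
#' @inheritParams match_comparators
#' @param registry_flags catastrophic-illness registry flags.
#' @return list: `cohort` (assignments), `exclusions`, `dropped_no_biopsy`.
#' @export
build_cohort <- function(claims, persons, registry_flags = NULL,
                         criteria = case_criteria(), ratio = 10L, seed = 1L) {
  cand <- identify_cases(claims, persons, criteria)
  excl <- apply_exclusions(cand, claims, registry_flags, criteria)
  dx <- explode_dx(claims)
  any_amyloid <- unique(dx[code %in% c(criteria$qualifying_codes,
                                       criteria$switch_codes,
                                       criteria$exclusion_codes_2015),
                           patient_id])
  pool <- setdiff(persons$patient_id, any_amyloid)
  cohort <- match_comparators(excl$kept, pool, persons, ratio = ratio,
                              seed = seed)
  list(cohort = cohort, exclusions = excl$excluded,
       dropped_no_biopsy = attr(cand, "dropped_no_biopsy"))
}
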