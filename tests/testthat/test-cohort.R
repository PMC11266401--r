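# Case identification, exclusions and exact matching.

test_that("the inpatient rule accepts secondary codes and sets the index date", {
  persons <- mk_persons(c("A", "B"))
  claims <- rbind(
    mk_claims("A", "2017-03-01", setting = "inpatient",
              dx_codes = "Z00.0|E85.9", dx_systems = "icd10|icd10",
              inpatient_days = 5L),
    mk_claims("A", "2017-02-19", proc_codes = "BX01"),    # biopsy 10 d before
    mk_claims("B", "2017-03-01")
  )
  cases <- identify_cases(claims, persons)
  expect_identical(cases$patient_id, "A")
  expect_identical(cases$index_date, as.Date("2017-03-01"))
})

test_that("the 30-day outpatient gap is a hard boundary", {
  persons <- mk_persons("A")
  base <- function(gap) rbind(
    mk_claims("A", "2017-01-01", dx_codes = "E85.4", proc_codes = "BX01"),
    mk_claims("A", as.character(as.Date("2017-01-01") + gap),
              dx_codes = "E85.4"))
  expect_identical(nrow(identify_cases(base(29), persons)), 0L)
  got <- identify_cases(base(30), persons)
  expect_identical(got$patient_id, "A")
  expect_identical(got$index_date, as.Date("2017-01-01"))
})

test_that("any-pair gap rule agrees with a brute-force all-pairs oracle", {
  set.seed(404)
  persons <- mk_persons("A")
  for (i in 1:60) {
    k <- sample(2:5, 1)
    days <- sort(sample(0:80, k))
    dates <- as.Date("2017-01-01") + days
    claims <- rbind(
      mk_claims(rep("A", k), dates, dx_codes = "E85.8"),
      mk_claims("A", "2017-01-05", proc_codes = "BX01"))
    qualifies_bf <- any(outer(days, days, function(a, b) abs(a - b) >= 30))
    got <- identify_cases(claims, persons)
    expect_identical(nrow(got) == 1L, qualifies_bf,
                     label = paste("days:", paste(days, collapse = ",")))
  }
})

test_that("the biopsy window is closed at both ends", {
  persons <- mk_persons("A")
  with_biopsy_at <- function(offset) rbind(
    mk_claims("A", "2017-06-01", setting = "inpatient", dx_codes = "E85.9",
              inpatient_days = 2L),
    mk_claims("A", as.character(as.Date("2017-06-01") + offset),
              proc_codes = "BX02"))
  expect_identical(nrow(identify_cases(with_biopsy_at(-365), persons)), 1L)
  expect_identical(nrow(identify_cases(with_biopsy_at(182), persons)), 1L)
  expect_identical(nrow(identify_cases(with_biopsy_at(-366), persons)), 0L)
  expect_identical(nrow(identify_cases(with_biopsy_at(183), persons)), 0L)
  dropped <- attr(identify_cases(with_biopsy_at(183), persons),
                  "dropped_no_biopsy")
  expect_identical(dropped, "A")
})

test_that("claims referencing unknown patients are rejected", {
  expect_error(identify_cases(mk_claims("GHOST", "2017-01-01"),
                              mk_persons("A")),
               "unknown patients")
})

test_that("exclusion reasons follow the fixed rule order", {
  persons <- mk_persons(c("P1", "P2", "P3", "P4"))
  qualify <- function(id) rbind(
    mk_claims(id, "2017-06-01", setting = "inpatient", dx_codes = "E85.4",
              proc_codes = "BX01", inpatient_days = 1L))
  claims <- rbind(
    qualify("P1"), mk_claims("P1", "2015-07-01", dx_codes = "277.3",
                             dx_systems = "icd9"),
    # P1 also has a post-index switch code: prior_2015 must win
    mk_claims("P1", "2017-08-01", dx_codes = "E85.0"),
    qualify("P2"), mk_claims("P2", "2017-09-01", dx_codes = "E83.3"),
    qualify("P3"),
    qualify("P4"))
  flags <- data.table(patient_id = "P4", flag_code = "E85.1",
                      flag_system = "icd10")
  cand <- identify_cases(claims, persons)
  res <- apply_exclusions(cand, claims, flags)
  expect_identical(res$kept$patient_id, "P3")
  expect_identical(res$excluded[patient_id == "P1", reason], "prior_2015")
  expect_identical(res$excluded[patient_id == "P2", reason], "switch")
  expect_identical(res$excluded[patient_id == "P4", reason], "registry")
  # a pre-index (not post-index) switch code does not exclude
  claims2 <- rbind(qualify("P3"), mk_claims("P3", "2017-01-01",
                                            dx_codes = "E85.2"))
  res2 <- apply_exclusions(identify_cases(claims2, mk_persons("P3")),
                           claims2, NULL)
  # index moves to the first qualifying-code claim only; E85.2 is not
  # qualifying, so the index stays at 2017-06-01 and the switch is pre-index
  expect_identical(res2$kept$patient_id, "P3")
})

test_that("planted exclusion patterns are recovered exactly on generator output", {
  cfg <- synthetic_config(n_cases = 150, rng_seed = 55)
  sim <- simulate_dataset(cfg)
  cand <- identify_cases(sim$claims, sim$persons)
  res <- apply_exclusions(cand, sim$claims, sim$registry_flags)
  truth <- sim$truth
  expect_setequal(res$kept$patient_id, truth[role == "case", patient_id])
  for (ty in c("prior_2015", "switch", "registry")) {
    expect_setequal(res$excluded[reason == ty, patient_id],
                    truth[role == paste0("trap_", ty), patient_id])
  }
  expect_setequal(attr(cand, "dropped_no_biopsy"),
                  truth[role == "trap_no_biopsy", patient_id])
  # index dates equal the planted ones
  m <- merge(res$kept, truth[, .(patient_id, planted = index_date)],
             by = "patient_id")
  expect_true(all(m$index_date == m$planted))
})

test_that("1:1 matching of a cloned pool pairs every case exactly", {
  persons <- rbind(
    mk_persons(paste0("C", 1:5), sex = rep(c("male", "female"), c(3, 2)),
               birth_date = as.Date("1950-01-01") + (1:5) * 400,
               region = c("Taipei", "North", "Taipei", "South", "East")),
    mk_persons(paste0("M", 1:5), sex = rep(c("male", "female"), c(3, 2)),
               birth_date = as.Date("1950-01-01") + (1:5) * 400,
               region = c("Taipei", "North", "Taipei", "South", "East")))
  cases <- data.table(patient_id = paste0("C", 1:5),
                      index_date = as.Date("2017-05-01"))
  got <- match_comparators(cases, paste0("M", 1:5), persons, ratio = 1,
                           seed = 3)
  expect_identical(nrow(got), 10L)
  expect_identical(sum(got$role == "comparator"), 5L)
  # each M_i is the unique demographic twin of C_i
  wide <- merge(got[role == "case", .(matched_set_id, case = patient_id)],
                got[role == "comparator", .(matched_set_id, comp = patient_id)],
                by = "matched_set_id")
  expect_identical(sub("M", "C", wide$comp), wide$case)
})

test_that("matching errors when the pool cannot support the ratio", {
  persons <- rbind(mk_persons("C1"), mk_persons(c("M1", "M2")))
  cases <- data.table(patient_id = "C1", index_date = as.Date("2017-05-01"))
  expect_error(match_comparators(cases, c("M1", "M2"), persons, ratio = 3,
                                 seed = 1),
               "insufficient comparator pool.*C1")
})

test_that("matching is deterministic, reuse-free and row-order invariant", {
  cfg <- synthetic_config(n_cases = 120, rng_seed = 66)
  sim <- simulate_dataset(cfg)
  b1 <- build_cohort(sim$claims, sim$persons, sim$registry_flags,
                     ratio = 10, seed = 5)
  b2 <- build_cohort(sim$claims, sim$persons, sim$registry_flags,
                     ratio = 10, seed = 5)
  expect_equal(b1$cohort, b2$cohort)
  expect_identical(anyDuplicated(b1$cohort$patient_id), 0L)
  expect_identical(nrow(b1$cohort[, .N, by = matched_set_id][N != 11L]), 0L)

  # shuffle input rows: assignment unchanged
  set.seed(1)
  sh_claims <- sim$claims[sample(.N)]
  sh_persons <- sim$persons[sample(.N)]
  b3 <- build_cohort(sh_claims, sh_persons, sim$registry_flags,
                     ratio = 10, seed = 5)
  expect_equal(b1$cohort, b3$cohort)

  # different seed: keys still exact, membership may differ
  b4 <- build_cohort(sim$claims, sim$persons, sim$registry_flags,
                     ratio = 10, seed = 6)
  m <- merge(b4$cohort, sim$persons, by = "patient_id")
  m[, age := completed_years(birth_date, index_date)]
  keys <- m[, .(ok = length(unique(paste(sex, region, age))) == 1L),
            by = matched_set_id]
  expect_true(all(keys$ok))
})
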