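# Baseline comorbidity ascertainment and the cohort comparison table.

# Prefix match of exploded dx rows against one category's code lists.
match_category <- function(dx, codelist) {
  hit <- rep(FALSE, nrow(dx))
  for (sys in c("icd9", "icd10")) {
    prefixes <- codelist[[sys]]
    if (is.null(prefixes)) next
    rows <- dx$system == sys
    for (p in prefixes) hit[rows] <- hit[rows] | startsWith(dx$code[rows], p)
  }
  hit
}

#' Flag baseline comorbidities
#'
#' An indicator is set for a category when the patient has at least one
#' inpatient claim or at least two outpatient claims carrying one of the
#' category's codes (prefix match, any diagnosis position) inside the
#' baseline window of 365 days before the index/reference date (the index
#' day itself excluded).  Unlike the case-identification rule there is no
#' distinct-date requirement: two same-day outpatient claims count as two.
#'
#' @param cohort cohort assignments (`patient_id`, `index_date`); roles are
#'   carried through if present.
#' @param claims claims table.
#' @param codelists named list of category code lists, see
#'   [default_codelists()]; categories must be the six canonical ones.
#' @return data.table with `patient_id` and one 0/1 column per category.
#' @export
flag_comorbidities <- function(cohort, claims, codelists = default_codelists()) {
  cats <- comorbidity_categories()
  if (!setequal(names(codelists), cats)) {
    stop("codelists must cover exactly the six categories: ",
         paste(cats, collapse = ", "), call. = FALSE)
  }
  cohort <- as.data.table(cohort)
  cl <- as.data.table(claims)[patient_id %in% cohort$patient_id]
  cl <- merge(cl, cohort[, .(patient_id, index_date)], by = "patient_id",
              allow.cartesian = TRUE)
  cl <- cl[service_date >= index_date - 365L & service_date <= index_date - 1L &
             setting %in% c("inpatient", "outpatient")]
  out <- cohort[, .(patient_id)]
  if (nrow(cl) > 0) dx <- explode_dx(cl)
  for (cat in cats) {
    col <- paste0("com_", cat)
    out[, (col) := 0L]
    if (nrow(cl) == 0) next
    hit <- dx[match_category(dx, codelists[[cat]])]
    if (nrow(hit) == 0) next
    # a claim with several category codes counts once
    hit <- unique(hit[, .(patient_id, claim_row, setting)])
    counts <- hit[, .(ip = sum(setting == "inpatient"),
                      op = sum(setting == "outpatient")), by = patient_id]
    flagged <- counts[ip >= 1L | op >= 2L, patient_id]
    out[patient_id %in% flagged, (col) := 1L]
  }
  setkey(out, patient_id)
  out[]
}

#' Baseline characteristics table with significance tests
#'
#' Summarises demographics and comorbidity indicators by cohort role:
#' frequencies and percentages for categorical variables with Pearson
#' chi-square tests (no continuity correction), mean, SD, median and
#' quartiles for age with a pooled-variance two-sample t-test (Welch
#' available via `welch = TRUE`).  Zero-variance continuous comparisons are
#' reported with `NA` p-values rather than failing.
#'
#' @param cohort cohort assignments with `role` column.
#' @param persons person registry.
#' @param profiles output of [flag_comorbidities()].
#' @param welch use Welch's t-test instead of pooled variance.
#' @return data.table with one row per variable/level and columns for both
#'   cohorts, the test statistic and the two-sided p-value.
#' @export
baseline_table <- function(cohort, persons, profiles, welch = FALSE) {
  cohort <- as.data.table(cohort)
  dt <- merge(cohort, as.data.table(persons), by = "patient_id")
  dt <- merge(dt, profiles, by = "patient_id")
  dt[, age_years := completed_years(birth_date, index_date)]
  dt[, age_cont := as.numeric(index_date - birth_date) / 365.25]
  grp <- factor(dt$role, levels = c("case", "comparator"))
  n_case <- sum(grp == "case"); n_comp <- sum(grp == "comparator")

  rows <- list()
  add_cat <- function(variable, x, positive = NULL) {
    if (!is.factor(x)) x <- factor(x)   # keep declared (possibly empty) levels
    tab <- table(x, grp)
    stat <- p <- NA_real_
    if (nrow(tab) >= 2 && all(colSums(tab) > 0)) {
      expected_ok <- all(rowSums(tab) > 0)
      if (expected_ok) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
        if (is.nan(p)) p <- NA_real_
      }
    } else if (nrow(tab) == 1) {
      stat <- 0; p <- 1   # identical degenerate distributions
    }
    levels_shown <- if (!is.null(positive)) positive else levels(x)
    rbindlist(lapply(levels_shown, function(lv) {
      data.table(variable = variable, level = lv,
                 case_n = as.integer(tab[lv, "case"]),
                 case_pct = 100 * tab[lv, "case"] / n_case,
                 comp_n = as.integer(tab[lv, "comparator"]),
                 comp_pct = 100 * tab[lv, "comparator"] / n_comp,
                 case_mean = NA_real_, case_sd = NA_real_,
                 comp_mean = NA_real_, comp_sd = NA_real_,
                 statistic = stat, p_value = p, test = "chi-square")
    }))
  }

  rows$sex <- add_cat("sex", dt$sex)
  # age in completed years: the matched quantity, so exactly matched cohorts
  # have identical means and the test statistic is exactly zero
  x <- dt$age_years
  m1 <- mean(x[grp == "case"]); m2 <- mean(x[grp == "comparator"])
  s1 <- stats::sd(x[grp == "case"]); s2 <- stats::sd(x[grp == "comparator"])
  if ((s1 > 0 || s2 > 0) && n_case > 1 && n_comp > 1) {
    tt <- t.test(x[grp == "case"], x[grp == "comparator"],
                 var.equal = !welch)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    stat <- NA_real_; p <- NA_real_
  }
  rows$age <- data.table(variable = "age_years", level = NA_character_,
                         case_n = n_case, case_pct = NA_real_,
                         comp_n = n_comp, comp_pct = NA_real_,
                         case_mean = m1, case_sd = s1,
                         comp_mean = m2, comp_sd = s2,
                         statistic = stat, p_value = p,
                         test = if (welch) "t (Welch)" else "t (pooled)")
  rows$region <- add_cat("region", dt$region)
  for (cat in comorbidity_categories()) {
    col <- paste0("com_", cat)
    rows[[col]] <- add_cat(col, factor(dt[[col]], levels = 0:1), positive = "1")
  }
  out <- rbindlist(rows)
  attr(out, "n") <- c(case = n_case, comparator = n_comp)
  out
}
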