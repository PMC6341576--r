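# The multi-step case-identification algorithm:
#   step 1 - first lung-cancer or small-cell-cancer (SCC) code during
#            follow-up assigns the patient to group 1 (lung code) or
#            group 2 (SCC code) and fixes the index date;
#   step 2 - patients with the complementary code type within +/-90 days of
#            the index code are retained as cross-code-confirmed cases and
#            skip the text search;
#   step 3 - the remaining patients' free-text comments are searched within
#            -30/+90 days of the index code for SCLC strings (group 1, with
#            negation handling) or lung-cancer strings (group 2);
#   step 4 - random samples of the text strata are reviewed manually and
#            the resulting confirmation rates are extrapolated to the whole
#            strata to give the expected number of incident SCLC cases.

#' Detect index codes and assign groups
#'
#' For each patient in the cohort, the earliest lung-cancer or SCC code
#' within follow-up (`[start_date, end_date]`; follow-up ends at the index
#' code, so the code on the end date itself counts) defines the
#' group: group 1 when it is a lung-cancer code, group 2 when it is an SCC
#' code. When both code types share the earliest date the SCC code wins
#' (the more specific code). Patients with no such code are absent.
#'
#' @param bundle An [ehr_bundle()].
#' @param followups Output of [eligible_cohort()].
#' @param codelist A [code_list()]; the `lung_cancer` and `scc` code sets
#'   must be disjoint (guaranteed by [code_list()]).
#' @return Data frame: `patient_id`, `group` (1 or 2), `index_code`,
#'   `index_date`.
#' @export
detect_index <- function(bundle, followups, codelist) {
  lung_codes <- codes_of(codelist, "lung_cancer")
  scc_codes <- codes_of(codelist, "scc")
  if (!length(lung_codes) || !length(scc_codes)) {
    stop_config("code list must contain both lung_cancer and scc codes")
  }
  ev <- data.table::as.data.table(bundle$events)
  fu <- data.table::as.data.table(followups)
  ev <- ev[code %in% c(lung_codes, scc_codes)]
  ev <- merge(ev, fu[, .(patient_id, start_date, end_date)], by = "patient_id")
  ev <- ev[event_date >= start_date & event_date <= end_date]
  if (!nrow(ev)) {
    return(data.table::data.table(patient_id = integer(), group = integer(),
                                  index_code = character(),
                                  index_date = as.Date(character())))
  }
  ev[, group := data.table::fifelse(code %in% scc_codes, 2L, 1L)]
  # earliest date wins; on a tie the SCC code (group 2) is preferred
  data.table::setorder(ev, patient_id, event_date, -group)
  idx <- unique(ev, by = "patient_id")
  out <- idx[, .(patient_id, group,
                 index_code = code, index_date = event_date)]
  data.table::setorder(out, patient_id)
  out[]
}

#' Cross-code confirmation within a symmetric day window
#'
#' A group-1 patient is flagged when any SCC code lies within
#' `[index - window_days, index + window_days]` (both ends inclusive);
#' group-2 patients symmetrically with lung-cancer codes. Flagged patients
#' are retained as confirmed cases and skip the free-text search.
#'
#' @param assignments Output of [detect_index()].
#' @param bundle An [ehr_bundle()].
#' @param codelist A [code_list()].
#' @param window_days Half-width of the window in days, default 90.
#' @return Data frame `patient_id`, `cross_code` (logical).
#' @export
cross_code <- function(assignments, bundle, codelist, window_days = 90L) {
  lung_codes <- codes_of(codelist, "lung_cancer")
  scc_codes <- codes_of(codelist, "scc")
  ev <- data.table::as.data.table(bundle$events)
  a <- data.table::as.data.table(assignments)
  ev <- ev[code %in% c(lung_codes, scc_codes)]
  ev <- merge(ev, a[, .(patient_id, group, index_date)], by = "patient_id")
  ev[, is_scc := code %in% scc_codes]
  ev[, off := abs(days_between(event_date, index_date))]
  hit <- ev[off <= window_days &
              ((group == 1L & is_scc) | (group == 2L & !is_scc)),
            unique(patient_id)]
  out <- a[, .(patient_id, cross_code = patient_id %in% hit)]
  data.table::setorder(out, patient_id)
  out[]
}

#' Classify patients into ascertainment strata
#'
#' Combines the group assignment, cross-code flag and free-text flags into
#' a single stratum per patient:
#' cross-code-confirmed patients get `cross_code_confirmed`; remaining
#' group-1 patients split into `text_sclc_only`, `text_non_only`,
#' `text_both` or `no_text` by their SCLC/negated flags; remaining group-2
#' patients are `text_lung` or `no_text`. `is_expected_case` is `TRUE` for
#' `cross_code_confirmed`, `text_sclc_only` and `text_lung`; `FALSE` for
#' `text_non_only` and `no_text`; `FALSE` for `text_both`, whose
#' contribution enters only through confirmation-rate extrapolation.
#'
#' @param assignments Output of [detect_index()].
#' @param cross_flags Output of [cross_code()].
#' @param text_flags Data frame `patient_id`, `has_sclc_text`,
#'   `has_non_text`, `has_lung_text` for the non-cross-confirmed patients
#'   (rows for cross-confirmed patients are ignored).
#' @return Data frame `patient_id`, `group`, `index_code`, `index_date`,
#'   `stratum`, `is_expected_case`.
#' @export
classify_cases <- function(assignments, cross_flags, text_flags) {
  a <- data.table::as.data.table(assignments)
  x <- merge(a, data.table::as.data.table(cross_flags), by = "patient_id")
  x <- merge(x, data.table::as.data.table(text_flags), by = "patient_id",
             all.x = TRUE)
  for (cc in c("has_sclc_text", "has_non_text", "has_lung_text")) {
    data.table::set(x, which(is.na(x[[cc]])), cc, FALSE)
  }
  x[, stratum := data.table::fcase(
    cross_code, "cross_code_confirmed",
    group == 1L & has_sclc_text & has_non_text, "text_both",
    group == 1L & has_sclc_text, "text_sclc_only",
    group == 1L & has_non_text, "text_non_only",
    group == 2L & has_lung_text, "text_lung",
    default = "no_text")]
  x[, is_expected_case := stratum %in%
      c("cross_code_confirmed", "text_sclc_only", "text_lung")]
  out <- x[, .(patient_id, group, index_code, index_date, stratum,
               is_expected_case)]
  data.table::setorder(out, patient_id)
  out[]
}

#' Aggregate classification counts
#'
#' Tallies the group sizes, cross-code counts and text-stratum counts that
#' flow through the ascertainment flowchart.
#'
#' @param classifications Output of [classify_cases()].
#' @return An object of class `sclc_step_counts`.
#' @export
step_counts <- function(classifications) {
  cl <- data.table::as.data.table(classifications)
  cnt <- function(g, s) sum(cl$group == g & cl$stratum == s)
  counts <- list(
    n_group1 = sum(cl$group == 1L),
    n_group2 = sum(cl$group == 2L),
    n_cross1 = cnt(1L, "cross_code_confirmed"),
    n_cross2 = cnt(2L, "cross_code_confirmed"),
    n_text_sclc_only = cnt(1L, "text_sclc_only"),
    n_text_non_only = cnt(1L, "text_non_only"),
    n_text_both = cnt(1L, "text_both"),
    n_text_lung = cnt(2L, "text_lung")
  )
  structure(counts, class = "sclc_step_counts")
}

#' Manually assembled step counts
#'
#' Builds an `sclc_step_counts` object from known counts, e.g. the counts
#' printed in a published flowchart, so the extrapolation can be applied to
#' them directly.
#'
#' @param n_group1,n_group2 Group sizes.
#' @param n_cross1,n_cross2 Cross-code-confirmed counts per group.
#' @param n_text_sclc_only,n_text_non_only,n_text_both,n_text_lung Text
#'   stratum counts.
#' @return An `sclc_step_counts` object.
#' @examples
#' make_step_counts(24508, 733, 364, 137, 2000, 4166, 353, 437)
#' @export
make_step_counts <- function(n_group1, n_group2, n_cross1, n_cross2,
                             n_text_sclc_only, n_text_non_only, n_text_both,
                             n_text_lung) {
  counts <- lapply(as.list(environment()), as.numeric)
  if (any(unlist(counts) < 0)) stop_param("counts must be non-negative")
  if (counts$n_cross1 > counts$n_group1 || counts$n_cross2 > counts$n_group2) {
    stop_param("cross-code counts cannot exceed group sizes")
  }
  if (counts$n_text_sclc_only + counts$n_text_non_only + counts$n_text_both >
      counts$n_group1 - counts$n_cross1 ||
      counts$n_text_lung > counts$n_group2 - counts$n_cross2) {
    stop_param("text stratum counts exceed residual group sizes")
  }
  structure(counts[c("n_group1", "n_group2", "n_cross1", "n_cross2",
                     "n_text_sclc_only", "n_text_non_only", "n_text_both",
                     "n_text_lung")],
            class = "sclc_step_counts")
}

#' Extrapolate confirmation rates to expected case counts
#'
#' Applies per-stratum confirmation rates to the text-stratum counts and
#' adds the cross-code-confirmed patients (taken as confirmed without
#' review). Each stratum contribution is rounded to the nearest integer
#' (half away from zero) before summation:
#'
#' `expected_cases_total = n_cross1 + round(rate_sclc_only * n_text_sclc_only)
#'   + round(rate_both * n_text_both) + n_cross2 + round(rate_lung * n_text_lung)`
#'
#' The ambiguous (`text_both`) contribution is excluded from the final
#' expected number: `expected_cases_final = expected_cases_total -
#' round(rate_both * n_text_both)`. Both totals are reported.
#'
#' @param counts An `sclc_step_counts` object.
#' @param rates Named list/vector of confirmation rates in `[0, 1]`:
#'   `sclc_only`, `both`, `lung`.
#' @return The `counts` object extended with `rates`, `term_sclc_only`,
#'   `term_both`, `term_lung`, `expected_cases_total`,
#'   `expected_cases_final`.
#' @examples
#' sc <- make_step_counts(24508, 733, 364, 137, 2000, 4166, 353, 437)
#' sc <- extrapolate_cases(sc, c(sclc_only = 1, both = 0.05, lung = 1))
#' sc$expected_cases_total  # 2956
#' sc$expected_cases_final  # 2938
#' @export
extrapolate_cases <- function(counts,
                              rates = c(sclc_only = 1, both = 0.05, lung = 1)) {
  stopifnot(inherits(counts, "sclc_step_counts"))
  rates <- as.list(rates)
  for (nm in c("sclc_only", "both", "lung")) {
    r <- rates[[nm]]
    if (is.null(r) || is.na(r) || r < 0 || r > 1) {
      stop_param("confirmation rate '", nm, "' must be in [0, 1]")
    }
  }
  counts$rates <- rates
  counts$term_sclc_only <- round_half_away(rates$sclc_only * counts$n_text_sclc_only)
  counts$term_both <- round_half_away(rates$both * counts$n_text_both)
  counts$term_lung <- round_half_away(rates$lung * counts$n_text_lung)
  counts$expected_cases_total <- counts$n_cross1 + counts$term_sclc_only +
    counts$term_both + counts$n_cross2 + counts$term_lung
  counts$expected_cases_final <- counts$expected_cases_total - counts$term_both
  counts
}

#' @export
print.sclc_step_counts <- function(x, ...) {
  cat("SCLC case ascertainment step counts\n")
  cat(sprintf("  step 1  group 1 (lung-cancer code): %d\n", x$n_group1))
  cat(sprintf("          group 2 (SCC code):         %d\n", x$n_group2))
  pct <- function(a, b) if (b > 0) sprintf(" (%.1f%%)", 100 * a / b) else ""
  cat(sprintf("  step 2  cross-coded, group 1: %d%s\n",
              x$n_cross1, pct(x$n_cross1, x$n_group1)))
  cat(sprintf("          cross-coded, group 2: %d%s\n",
              x$n_cross2, pct(x$n_cross2, x$n_group2)))
  cat(sprintf("  step 3  group 1 'SCLC' text only: %d\n", x$n_text_sclc_only))
  cat(sprintf("          group 1 'non' text only:  %d\n", x$n_text_non_only))
  cat(sprintf("          group 1 both strings:     %d\n", x$n_text_both))
  cat(sprintf("          group 2 'lung cancer' text: %d\n", x$n_text_lung))
  if (!is.null(x$expected_cases_total)) {
    cat(sprintf("  step 4  expected cases, total: %d (ambiguous term %d)\n",
                x$expected_cases_total, x$term_both))
    cat(sprintf("          expected cases, final: %d\n",
                x$expected_cases_final))
  }
  invisible(x)
}

#' Backdate the final event date to the first related record
#'
#' The assigned SCLC event date is the earliest of the dates of
#' symptom-coded, diagnostic-procedure-coded or surgery-coded events within
#' `[recorded_date - lookback_days, recorded_date]`, or the recorded index
#' date itself when no such record exists. Never later than
#' `recorded_date`.
#'
#' @param events One patient's events (`event_date`, `code`).
#' @param codelist A [code_list()] tagging `symptom`, `procedure`,
#'   `surgery` codes.
#' @param recorded_date The index-code date.
#' @param lookback_days How far back related records may move the date;
#'   default 90 days.
#' @return A `Date` of length 1.
#' @export
backdate_event_date <- function(events, codelist, recorded_date,
                                lookback_days = 90L) {
  recorded_date <- as_date(recorded_date)
  rel <- codes_of(codelist, c("symptom", "procedure", "surgery"))
  d <- as_date(events$event_date[events$code %in% rel])
  d <- d[d >= recorded_date - lookback_days & d <= recorded_date]
  if (!length(d)) recorded_date else min(d)
}

# Vectorised backdating for the whole case set.
backdate_all <- function(bundle, classifications, codelist,
                         lookback_days = 90L) {
  cl <- data.table::as.data.table(classifications)
  rel <- codes_of(codelist, c("symptom", "procedure", "surgery"))
  ev <- data.table::as.data.table(bundle$events)[code %in% rel]
  ev <- merge(ev, cl[, .(patient_id, index_date)], by = "patient_id")
  ev <- ev[event_date >= index_date - as.integer(lookback_days) &
             event_date <= index_date]
  bd <- if (nrow(ev)) {
    ev[, .(backdated = min(event_date)), by = patient_id]
  } else {
    data.table::data.table(patient_id = integer(),
                           backdated = as.Date(character()))
  }
  out <- merge(cl, bd, by = "patient_id", all.x = TRUE)
  out[, final_event_date := data.table::fifelse(is.na(backdated),
                                                index_date, backdated)]
  out[, backdated := NULL]
  data.table::setorder(out, patient_id)
  out[]
}
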