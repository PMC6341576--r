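# Cohort eligibility and person-time.

add_years <- function(d, k) {
  lt <- as.POSIXlt(as_date(d))
  lt$year <- lt$year + k
  as.Date(lt)  # Feb 29 rolls forward in non-leap years
}

#' Build the eligible cohort with start dates and follow-up intervals
#'
#' A patient enters the cohort at the earliest date within
#' `[study_start, study_end]` at which all of the following hold: age is
#' within `age_range` (entry criterion only; follow-up is not truncated at
#' the upper age), registration status is permanent or died, at least
#' `enrolment_days` have passed since registration, at least `rx_days`
#' since the first recorded prescription, at least one clinical event was
#' recorded in the preceding `encounter_days` (inclusive of the date
#' itself), and no lung-cancer or small-cell-cancer code was recorded
#' before that date. Follow-up runs from the start date to the earliest of
#' the first qualifying cancer code, death, or `study_end` (half-open
#' interval: a code on the start date itself counts as during follow-up,
#' giving zero person-days). Patients never satisfying the criteria are
#' absent from the result.
#'
#' @param bundle An [ehr_bundle()].
#' @param codelist A [code_list()] tagging `lung_cancer` and `scc` codes.
#' @param study_start,study_end Study window bounds.
#' @param enrolment_days,rx_days,encounter_days Eligibility thresholds in
#'   days; defaults are two years = 730 days.
#' @param age_range Entry age band, default `c(18, 89)` in completed years.
#' @return A data frame of follow-up intervals: `patient_id`, `start_date`,
#'   `end_date`, `end_reason` (`"index_code"`, `"death"`, `"study_end"`),
#'   `person_days`.
#' @export
eligible_cohort <- function(bundle, codelist,
                            study_start = "2000-01-01",
                            study_end = "2014-12-31",
                            enrolment_days = 730L, rx_days = 730L,
                            encounter_days = 730L, age_range = c(18L, 89L)) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  d0 <- as_date(study_start)
  d1 <- as_date(study_end)
  if (d0 >= d1) stop_param("'study_start' must precede 'study_end'")

  p <- data.table::as.data.table(bundle$patients)
  ev <- data.table::as.data.table(bundle$events)
  orphan <- setdiff(ev$patient_id, p$patient_id)
  if (length(orphan)) {
    stop_linkage("events refer to patient(s) absent from the patients ",
                 "table, e.g. ", orphan[1])
  }

  p <- p[registration_status %in% c("permanent", "died")]
  if (!nrow(p)) {
    return(empty_followups())
  }

  agg_min <- function(dt, datecol, out) {
    if (!nrow(dt)) {
      res <- data.table::data.table(patient_id = integer(),
                                    x = as.Date(character()))
    } else {
      res <- dt[, .(x = min(get(datecol))), by = patient_id]
    }
    data.table::setnames(res, "x", out)
  }
  rx1 <- agg_min(data.table::as.data.table(bundle$prescriptions),
                 "issue_date", "first_rx")
  cancer_codes <- codes_of(codelist, c("lung_cancer", "scc"))
  ca1 <- agg_min(ev[code %in% cancer_codes], "event_date", "first_cancer")
  p <- merge(p, rx1, by = "patient_id", all.x = TRUE)
  p <- merge(p, ca1, by = "patient_id", all.x = TRUE)

  # earliest date all waiting-period criteria hold
  p[, base := pmax(d0,
                   registration_start + as.integer(enrolment_days),
                   data.table::fifelse(is.na(first_rx), d0,
                                       first_rx + as.integer(rx_days)),
                   add_years(birth_date, age_range[1]))]
  # a patient with no prescription has no "first prescription" waiting
  # period to serve; spec criteria require one, so drop them
  p <- p[!is.na(first_rx)]
  # earliest clinical event on/after base - encounter_days
  data.table::setorder(ev, patient_id, event_date)
  p[, lb := base - as.integer(encounter_days)]
  enc <- ev[p, on = .(patient_id, event_date >= lb),
            .(patient_id = i.patient_id, enc_date = x.event_date),
            mult = "first"]
  p[, enc_date := enc$enc_date]
  p <- p[!is.na(enc_date)]
  p[, start_date := pmax(base, enc_date)]

  # entry bounds: within the window, alive, under the age cap, cancer-free
  p <- p[start_date <= d1]
  p <- p[is.na(death_date) | death_date >= start_date]
  p <- p[age_at(birth_date, start_date) <= age_range[2]]
  p <- p[is.na(first_cancer) | first_cancer >= start_date]

  if (!nrow(p)) return(empty_followups())

  p[, end_date := pmin(d1,
                       data.table::fifelse(is.na(death_date),
                                           as.Date("9999-12-31"), death_date),
                       data.table::fifelse(is.na(first_cancer),
                                           as.Date("9999-12-31"), first_cancer))]
  p[, end_reason := data.table::fcase(
    !is.na(first_cancer) & first_cancer == end_date, "index_code",
    !is.na(death_date) & death_date == end_date, "death",
    default = "study_end")]
  p[, person_days := days_between(end_date, start_date)]
  out <- p[, .(patient_id, start_date, end_date, end_reason, person_days)]
  data.table::setorder(out, patient_id)
  out[]
}

empty_followups <- function() {
  data.table::data.table(patient_id = integer(),
                         start_date = as.Date(character()),
                         end_date = as.Date(character()),
                         end_reason = character(),
                         person_days = integer())
}

#' Total person-years of follow-up
#'
#' Sum of follow-up days divided by 365 (the package's person-year
#' convention).
#'
#' @param followups Output of [eligible_cohort()].
#' @return Person-years as a single number.
#' @export
total_person_years <- function(followups) {
  if (is.null(followups) || !nrow(followups)) return(0)
  sum(as.numeric(followups$person_days)) / DAYS_PER_YEAR
}
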