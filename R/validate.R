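# Simulated manual-review validation: stratum samples, confirmation rates,
# positive predictive values with exact binomial intervals, and the
# exclusion-reason tally.

#' Draw a random review sample from a stratum
#'
#' Simple random sample without replacement of patient ids from one
#' classification stratum, deterministic under the seed.
#'
#' @param classifications Output of [classify_cases()].
#' @param stratum Stratum name (e.g. `"text_sclc_only"`).
#' @param size Sample size; must not exceed the stratum count.
#' @param seed Integer seed.
#' @return Integer vector of patient ids.
#' @export
draw_review_sample <- function(classifications, stratum, size, seed = 1L) {
  ids <- classifications$patient_id[classifications$stratum == stratum]
  if (size > length(ids)) {
    stop_param("sample size ", size, " exceeds stratum '", stratum,
               "' count ", length(ids))
  }
  if (size == 0) return(integer())
  set.seed(as.integer(seed))
  sort(sample(ids, size))
}

#' Simulate manual chart review against ground truth
#'
#' In the synthetic setting the reviewer reads the truth labels: a patient
#' is confirmed as an incident SCLC case iff `true_disease == "SCLC"` and
#' the true onset falls within the patient's follow-up (on or after the
#' start date). Unconfirmed patients get an exclusion reason: `nsclc` for
#' true NSCLC, `prevalent` for SCLC with onset before follow-up start,
#' `other_location` for small-cell disease at another site, `unconfirmed`
#' when no cancer supports the record. An optional review error rate flips
#' each verdict independently, modelling imperfect chart review.
#'
#' @param sample_ids Patient ids to review.
#' @param bundle An [ehr_bundle()] with truth labels.
#' @param followups Output of [eligible_cohort()].
#' @param review_error_rate Probability a verdict flips; default 0.
#' @param seed Seed used when `review_error_rate > 0`.
#' @return Data frame `patient_id`, `reviewed`, `confirmed`,
#'   `exclusion_reason` (`"none"` iff confirmed).
#' @export
review_cases <- function(sample_ids, bundle, followups,
                         review_error_rate = 0, seed = 1L) {
  if (review_error_rate < 0 || review_error_rate > 1) {
    stop_param("'review_error_rate' must be in [0, 1]")
  }
  tr <- data.table::as.data.table(bundle$truth)
  fu <- data.table::as.data.table(followups)
  out <- data.table::data.table(patient_id = as.integer(sample_ids))
  out <- merge(out, tr, by = "patient_id", all.x = TRUE)
  if (any(is.na(out$true_disease))) {
    stop_linkage("no truth label for patient(s) ",
                 paste(utils::head(out$patient_id[is.na(out$true_disease)], 3),
                       collapse = ", "))
  }
  out <- merge(out, fu[, .(patient_id, start_date)], by = "patient_id",
               all.x = TRUE)
  out[, incident := !is.na(true_onset_date) & !is.na(start_date) &
        true_onset_date >= start_date]
  out[, confirmed := true_disease == "SCLC" & incident]
  out[, exclusion_reason := data.table::fcase(
    confirmed, "none",
    true_disease == "SCLC" & !incident, "prevalent",
    true_disease == "NSCLC", "nsclc",
    true_disease == "OTHER_LUNG", "other_location",
    default = "unconfirmed")]
  if (review_error_rate > 0) {
    set.seed(as.integer(seed))
    flip <- stats::runif(nrow(out)) < review_error_rate
    out[flip, `:=`(confirmed = !confirmed,
                   exclusion_reason = data.table::fifelse(confirmed,
                                                          "unconfirmed",
                                                          "none"))]
  }
  out[, reviewed := TRUE]
  res <- out[, .(patient_id, reviewed, confirmed, exclusion_reason)]
  data.table::setorder(res, patient_id)
  res[]
}

#' Positive predictive value with an exact binomial interval
#'
#' `ppv = n_confirmed / n_reviewed`, with a two-sided Clopper-Pearson
#' interval at the requested level.
#'
#' @param outcomes Output of [review_cases()], or `NULL` when supplying
#'   counts directly.
#' @param n_confirmed,n_reviewed Direct counts (used when `outcomes` is
#'   `NULL`); `n_reviewed` must be at least 1.
#' @param conf_level Interval coverage, default 0.95.
#' @return Object of class `sclc_ppv`: `n_confirmed`, `n_reviewed`, `ppv`,
#'   `ci_low`, `ci_high`.
#' @examples
#' ppv_estimate(n_confirmed = 381, n_reviewed = 400)
#' @export
ppv_estimate <- function(outcomes = NULL, n_confirmed = NULL,
                         n_reviewed = NULL, conf_level = 0.95) {
  if (!is.null(outcomes)) {
    n_reviewed <- sum(outcomes$reviewed)
    n_confirmed <- sum(outcomes$confirmed & outcomes$reviewed)
  }
  if (is.null(n_reviewed) || n_reviewed < 1) {
    stop_param("PPV is undefined with no reviewed patients")
  }
  ci <- clopper_pearson(n_confirmed, n_reviewed, conf_level)
  structure(list(n_confirmed = as.integer(n_confirmed),
                 n_reviewed = as.integer(n_reviewed),
                 ppv = n_confirmed / n_reviewed,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 conf_level = conf_level),
            class = "sclc_ppv")
}

#' @export
print.sclc_ppv <- function(x, ...) {
  cat(sprintf("PPV: %d/%d = %.1f%% (%d%% CI %.1f-%.1f%%)\n",
              x$n_confirmed, x$n_reviewed, 100 * x$ppv,
              round(100 * x$conf_level), 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Stratified positive predictive values
#'
#' PPV per level of a stratification variable (age band, sex, smoking
#' status, ...).
#'
#' @param outcomes Output of [review_cases()].
#' @param strata Vector aligned with `outcomes` rows giving each reviewed
#'   patient's stratum.
#' @param conf_level Interval coverage.
#' @return Named list of `sclc_ppv` objects, one per stratum level.
#' @export
stratified_ppv <- function(outcomes, strata, conf_level = 0.95) {
  stopifnot(length(strata) == nrow(outcomes))
  lapply(split(seq_len(nrow(outcomes)), strata), function(i) {
    ppv_estimate(outcomes[i, ], conf_level = conf_level)
  })
}

#' Per-stratum confirmation rates
#'
#' Confirmed/reviewed per stratum, as probabilities that feed
#' [extrapolate_cases()]. Errors on an empty stratum sample (the rate is
#' undefined).
#'
#' @param outcomes_by_stratum Named list of [review_cases()] outputs, one
#'   per stratum.
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
confirmation_rates <- function(outcomes_by_stratum) {
  vapply(names(outcomes_by_stratum), function(nm) {
    o <- outcomes_by_stratum[[nm]]
    if (is.null(o) || !nrow(o)) {
      stop_param("confirmation rate undefined for empty stratum sample '",
                 nm, "'")
    }
    sum(o$confirmed) / nrow(o)
  }, numeric(1))
}

#' Tally exclusion reasons among unconfirmed reviewed patients
#'
#' @param outcomes Output of [review_cases()].
#' @return Named integer vector of counts per exclusion reason.
#' @export
exclusion_tally <- function(outcomes) {
  reasons <- c("nsclc", "secondary_tumour", "prevalent", "unconfirmed",
               "other_location")
  tab <- table(factor(outcomes$exclusion_reason[!outcomes$confirmed],
                      levels = reasons))
  stats::setNames(as.integer(tab), reasons)
}
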