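# Incidence, one-year mortality, survival and baseline characterisation.

#' Incidence rate with a log-normal confidence interval
#'
#' `rate = events / person_time * scale`. The 95% interval is
#' `exp(log(rate) +/- 1.96 / sqrt(events))`; with zero events the exact
#' Poisson upper bound `3.69 / person_time * scale` is used with a lower
#' bound of 0.
#'
#' @param events Number of incident cases.
#' @param person_time Positive person-time denominator.
#' @param scale Reporting scale (default 10,000, i.e. per 10,000
#'   person-years when `person_time` is in person-years).
#' @param unit Label for the person-time unit.
#' @param conf_level Interval coverage.
#' @return Object of class `sclc_rate`: `events`, `person_time`, `unit`,
#'   `scale`, `rate`, `ci_low`, `ci_high`.
#' @examples
#' incidence_rate(2938, 29028641)  # about 1.01 per 10,000 person-years
#' @export
incidence_rate <- function(events, person_time, scale = 10000,
                           unit = "person-years", conf_level = 0.95) {
  if (!is.numeric(person_time) || person_time <= 0) {
    stop_param("'person_time' must be positive")
  }
  if (events < 0) stop_param("'events' must be non-negative")
  ci <- rate_ci(events, person_time, scale, conf_level)
  structure(list(events = events, person_time = person_time, unit = unit,
                 scale = scale, rate = events / person_time * scale,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 conf_level = conf_level),
            class = "sclc_rate")
}

#' @export
print.sclc_rate <- function(x, ...) {
  cat(sprintf("%d events / %.1f %s: %.2f per %s %s (%d%% CI %.2f-%.2f)\n",
              x$events, x$person_time, x$unit, x$rate,
              format(x$scale, big.mark = ","), x$unit,
              round(100 * x$conf_level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Build one-year mortality/survival records for the case set
#'
#' Each case is followed from its final (backdated) event date for up to 12
#' months; follow-up ends at death, at the end of the patient's record
#' (registration end, for patients whose practice stopped contributing
#' data), or at 12 months, whichever comes first. Cases whose record ends
#' on/before the final event date are excluded (no follow-up observable).
#' Time is measured in months of 30.4375 days.
#'
#' @param bundle An [ehr_bundle()].
#' @param cases Data frame with `patient_id` and `final_event_date` (e.g.
#'   classified expected cases after [backdate_all()]).
#' @param max_months Follow-up truncation, default 12.
#' @return Data frame `patient_id`, `sex`, `age_band`, `time_months`,
#'   `event` (death observed).
#' @export
survival_records <- function(bundle, cases, max_months = 12) {
  p <- data.table::as.data.table(bundle$patients)
  x <- merge(data.table::as.data.table(cases)[, .(patient_id,
                                                  final_event_date)],
             p, by = "patient_id")
  if (any(is.na(x$final_event_date))) {
    stop_linkage("case without a final event date")
  }
  x[, record_end := registration_end]  # NA means record continues
  x <- x[is.na(record_end) | record_end > final_event_date]
  x[, days := data.table::fifelse(
    !is.na(death_date),
    days_between(death_date, final_event_date),
    data.table::fifelse(!is.na(record_end),
                        days_between(record_end, final_event_date),
                        as.integer(ceiling(max_months * DAYS_PER_MONTH))))]
  x[, time_months := pmin(days / DAYS_PER_MONTH, max_months)]
  x[, event := !is.na(death_date) &
      days_between(death_date, final_event_date) / DAYS_PER_MONTH <= max_months]
  age <- age_at(x$birth_date, x$final_event_date)
  x[, age_band := cut(age, c(-Inf, 59, 69, 79, Inf),
                      labels = c("<60", "60-69", "70-79", ">=80"))]
  out <- x[, .(patient_id, sex, age_band = as.character(age_band),
               time_months, event)]
  data.table::setorder(out, patient_id)
  out[]
}

#' One-year all-cause mortality summary, stratified by sex and age band
#'
#' For the total column and each sex and age stratum: number at risk,
#' deaths within follow-up, crude cumulative mortality
#' (deaths / at risk, %), person-months of observation, and the mortality
#' rate per `scale` person-months with a log-normal interval.
#'
#' @param records Output of [survival_records()].
#' @param scale Rate scale, default 100 (per 100 person-months).
#' @param conf_level Interval coverage.
#' @return Data frame with one row per stratum (first row `total`):
#'   `stratum`, `at_risk`, `deaths`, `crude_pct`, `person_months`, `rate`,
#'   `ci_low`, `ci_high`.
#' @export
mortality_summary <- function(records, scale = 100, conf_level = 0.95) {
  r <- data.table::as.data.table(records)
  one <- function(sub, label) {
    n <- nrow(sub)
    d <- sum(sub$event)
    pm <- sum(sub$time_months)
    if (n == 0 || pm <= 0) {
      return(data.table::data.table(stratum = label, at_risk = n, deaths = d,
                                    crude_pct = NA_real_, person_months = pm,
                                    rate = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_))
    }
    ci <- rate_ci(d, pm, scale, conf_level)
    data.table::data.table(stratum = label, at_risk = n, deaths = d,
                           crude_pct = 100 * d / n, person_months = pm,
                           rate = d / pm * scale,
                           ci_low = unname(ci["low"]),
                           ci_high = unname(ci["high"]))
  }
  strata <- c(list(one(r, "total")),
              lapply(c("M", "F"), function(s) one(r[sex == s], s)),
              lapply(unique_bands(r$age_band),
                     function(a) one(r[age_band == a], a)))
  data.table::rbindlist(strata)[]
}

unique_bands <- function(x) {
  lv <- c("<60", "60-69", "70-79", ">=80")
  lv[lv %in% unique(x)]
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Direct implementation of the product-limit estimator:
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, where `d_i`
#' deaths occur at `t_i` among `n_i` still at risk (subjects censored at
#' `t_i` remain in the risk set for the deaths at `t_i`). The median
#' survival is the first event time at which `S(t) <= 0.5`, `NA` when
#' survival never reaches 0.5.
#'
#' @param records Data frame with `time_months` (non-negative) and `event`
#'   (logical, `TRUE` = death).
#' @return Object of class `sclc_km`: data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (rows at event times), plus
#'   attributes `median_survival` and `n`.
#' @examples
#' km <- km_estimate(data.frame(time_months = 1:4, event = TRUE))
#' summary(km)
#' @export
km_estimate <- function(records) {
  t <- as.numeric(records$time_months)
  e <- as.logical(records$event)
  if (any(is.na(t)) || any(t < 0)) {
    stop_param("survival times must be non-negative")
  }
  ut <- sort(unique(t[e]))
  n_risk <- integer(length(ut))
  n_event <- integer(length(ut))
  n_censor <- integer(length(ut))
  for (i in seq_along(ut)) {
    n_risk[i] <- sum(t >= ut[i])
    n_event[i] <- sum(e & t == ut[i])
    n_censor[i] <- sum(!e & t == ut[i])
  }
  surv <- cumprod(1 - n_event / pmax(n_risk, 1L))
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  structure(
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = surv),
    median_survival = med, n = length(t),
    class = c("sclc_km", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km An `sclc_km` object.
#' @param times Numeric vector of times.
#' @return Survival probabilities (step function, right-continuous).
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$survival[max(i)]
  }, numeric(1))
}

#' @export
print.sclc_km <- function(x, ...) {
  med <- attr(x, "median_survival")
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d event times, median = %s\n",
              attr(x, "n"), nrow(x),
              if (is.na(med)) "not reached" else sprintf("%.2f", med)))
  invisible(x)
}

#' @export
summary.sclc_km <- function(object, ...) {
  med <- attr(object, "median_survival")
  cat(sprintf("n = %d subjects, %d deaths\n", attr(object, "n"),
              sum(object$n_event)))
  cat(sprintf("median survival: %s\n",
              if (is.na(med)) "not reached" else sprintf("%.2f", med)))
  invisible(as.data.frame(object))
}

#' @export
plot.sclc_km <- function(x, xlab = "Months since diagnosis",
                         ylab = "Survival probability", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), main = "", ...)
  invisible(x)
}

#' Baseline characterisation of the case set
#'
#' Builds the characterisation table for a set of cases with final event
#' (diagnosis) dates, applying the standard recency rules: for lifestyle
#' variables (smoking, BMI, alcohol) the status closest before or on the
#' diagnosis date (category `"unknown"` when never recorded); comorbidities
#' as any code ever before diagnosis; medications as current use, i.e. the
#' supply of the most recent prescription of the class lasted until the
#' diagnosis date or ended within the previous 365 days. Age is binned as
#' `<50`, `50-59`, `60-69`, `70-79`, `80-89`.
#'
#' @param bundle An [ehr_bundle()].
#' @param cases Data frame with `patient_id` and `final_event_date`.
#' @param codelist A [code_list()] whose `lifestyle` and `comorbidity`
#'   codes carry `label`s (`"variable:category"` for lifestyle).
#' @return Data frame `variable`, `category`, `n`, `pct` (percentages of
#'   the case count, 1 decimal).
#' @export
baseline_table <- function(bundle, cases, codelist = default_codes()) {
  cs <- data.table::as.data.table(cases)[, .(patient_id, final_event_date)]
  if (any(is.na(cs$final_event_date))) {
    stop_linkage("case without a final event date")
  }
  n_cases <- nrow(cs)
  p <- merge(cs, data.table::as.data.table(bundle$patients),
             by = "patient_id")
  ev <- merge(data.table::as.data.table(bundle$events), cs,
              by = "patient_id")
  ev <- ev[event_date <= final_event_date]  # history only

  rows <- list()
  add_row <- function(variable, category, n) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      variable = variable, category = category, n = as.integer(n),
      pct = round(100 * n / n_cases, 1))
  }

  # sex and age bands
  for (s in c("M", "F")) add_row("sex", s, sum(p$sex == s))
  age <- age_at(p$birth_date, p$final_event_date)
  bands <- cut(age, c(-Inf, 49, 59, 69, 79, 89),
               labels = c("<50", "50-59", "60-69", "70-79", "80-89"))
  for (b in levels(bands)) add_row("age", b, sum(bands == b, na.rm = TRUE))

  # lifestyle: latest record on/before diagnosis
  life <- codelist[codelist$category == "lifestyle", ]
  lev <- ev[code %in% life$code]
  if (nrow(lev)) {
    lev[, label := life$label[match(code, life$code)]]
    lev[, c("variable", "category") := data.table::tstrsplit(label, ":",
                                                             fixed = TRUE)]
    data.table::setorder(lev, patient_id, variable, event_date)
    latest <- lev[, .SD[.N], by = .(patient_id, variable),
                  .SDcols = "category"]
  } else {
    latest <- data.table::data.table(patient_id = integer(),
                                     variable = character(),
                                     category = character())
  }
  for (v in unique(life_vars <- sub(":.*", "", life$label))) {
    cats <- sub(".*:", "", life$label[life_vars == v])
    sub <- latest[variable == v]
    for (cat_ in unique(cats)) add_row(v, cat_, sum(sub$category == cat_))
    add_row(v, "unknown", n_cases - nrow(sub))
  }

  # comorbidities: any code ever before diagnosis
  com <- codelist[codelist$category == "comorbidity", ]
  for (k in seq_len(nrow(com))) {
    add_row("comorbidity", com$label[k],
            length(unique(ev[code == com$code[k], patient_id])))
  }

  # medications: current use at diagnosis
  rx <- merge(data.table::as.data.table(bundle$prescriptions), cs,
              by = "patient_id")
  rx <- rx[issue_date <= final_event_date]
  rx[, ends := issue_date + supply_days]
  cur <- rx[ends >= final_event_date - 365L]
  for (cl in sort(unique(bundle$prescriptions$drug_class))) {
    add_row("medication", cl, length(unique(cur[drug_class == cl,
                                                patient_id])))
  }

  data.table::rbindlist(rows)[]
}
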