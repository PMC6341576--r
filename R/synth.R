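# Synthetic primary-care EHR generator.
#
# Emulates the structure of a UK primary-care database extract: per-patient
# registration intervals, dated Read-style coded events optionally carrying
# free-text comments, prescriptions with supply durations, death dates, and
# ground-truth disease labels that drive coding and text behaviour. The
# generator exists so that every downstream stage (cohort, text mining,
# ascertainment, validation, epi statistics) can be exercised and
# parameter-recovery can be checked against a known truth.

#' Default free-text comment templates
#'
#' Template sentences the generator attaches to note events. The sets
#' deliberately include spelling/formatting variants (hyphenated forms,
#' abbreviations) and, for the ambiguous set, comments containing both an
#' SCLC string and a negated form, so the matcher is stress-tested.
#' @return Named list of character vectors
#'   (`sclc`, `non`, `ambiguous`, `lung`).
#' @export
default_templates <- function() {
  list(
    sclc = c("ct chest: small cell lung cancer, extensive stage",
             "biopsy confirmed sclc",
             "small-cell ca of bronchus seen by oncology",
             "histology: small cell carcinoma",
             "oat cell carcinoma on cytology"),
    non = c("non small cell lung cancer on histology",
            "non-small cell ca, refer oncology",
            "nsclc confirmed, for staging",
            "biopsy: non small cell ca"),
    ambiguous = c("?sclc vs nsclc, awaiting histology",
                  "small cell ca vs non small cell ca - histology pending"),
    lung = c("lung cancer confirmed, oncology referral",
             "ca lung on imaging",
             "bronchial carcinoma, palliative plan",
             "lung ca - mdt discussion")
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic EHR generator. Defaults are set to the
#' magnitudes reported for UK primary care: a true SCLC hazard of 1.01 per
#' 10,000 person-years, roughly 7 NSCLC per SCLC, near-complete free-text
#' recording of a new SCLC diagnosis, 84.5% of cases with a recorded
#' symptom preceding the coded diagnosis, and a median case survival of
#' 7.37 months.
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param study_start,study_end Calendar bounds of the study window.
#' @param annual_sclc_hazard True SCLC onset hazard per person-year at risk.
#' @param nsclc_to_sclc_ratio Ratio of the NSCLC hazard to the SCLC hazard.
#' @param other_lung_to_sclc_ratio Ratio of the hazard of other small-cell
#'   malignancies (non-lung site, coded with small-cell-cancer codes) to the
#'   SCLC hazard.
#' @param p_code_lung_given_sclc,p_code_scc_given_sclc Probabilities that a
#'   true SCLC case's index code is a lung-cancer code or a small-cell
#'   cancer code (must sum to at most 1; remainder receives no code).
#' @param p_code_lung_given_nsclc Probability an NSCLC case receives a
#'   lung-cancer index code.
#' @param p_code_scc_given_other Probability an other-site small-cell case
#'   receives a small-cell-cancer index code.
#' @param p_cross_code Probability a coded SCLC case also receives the
#'   complementary code type within +/-90 days of the index code.
#' @param p_text_sclc Probability a lung-coded SCLC case gets a free-text
#'   comment with an SCLC string within the -30/+90-day window.
#' @param p_text_non Probability an NSCLC case gets a comment with a
#'   negated ("non ...") string.
#' @param p_text_lung Probability an SCC-coded SCLC case gets a comment
#'   with a lung-cancer string.
#' @param p_text_lung_given_other As above for other-site small-cell cases.
#' @param p_ambiguous_nsclc,p_ambiguous_sclc Probability the comment is an
#'   ambiguous one containing both an SCLC string and a negated string.
#' @param p_symptom_before Probability a case has a coded symptom at onset,
#'   with the diagnosis code recorded only after a lead time.
#' @param symptom_lead_days_max Maximum diagnostic lead time in days
#'   (uniform on 1..max; the default gives a median backdating of about 36
#'   days).
#' @param median_survival_months Baseline median survival of SCLC cases.
#' @param censor_dropout_rate Probability a case's record stops (practice
#'   data feed ends) 30-360 days after the index code, censoring mortality
#'   follow-up.
#' @param background_death_hazard Non-cancer death hazard per person-year.
#' @param transfer_rate Probability a patient transfers out of the practice
#'   at a uniform time (status `"transferred"`, excluded from the cohort).
#' @param visit_rate_per_year Mean routine-visit rate per person-year.
#' @param registration_lookback_days How far before `study_start`
#'   registrations may begin.
#' @param templates Free-text template sets, see [default_templates()].
#' @param seed Integer RNG seed; identical configs give identical bundles.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 10000,
                       study_start = "2000-01-01",
                       study_end = "2014-12-31",
                       annual_sclc_hazard = 1.01e-4,
                       nsclc_to_sclc_ratio = 7,
                       other_lung_to_sclc_ratio = 0.15,
                       p_code_lung_given_sclc = 0.8,
                       p_code_scc_given_sclc = 0.2,
                       p_code_lung_given_nsclc = 0.9,
                       p_code_scc_given_other = 0.7,
                       p_cross_code = 0.15,
                       p_text_sclc = 0.99,
                       p_text_non = 0.2,
                       p_text_lung = 0.98,
                       p_text_lung_given_other = 0.5,
                       p_ambiguous_nsclc = 0.015,
                       p_ambiguous_sclc = 0.002,
                       p_symptom_before = 0.845,
                       symptom_lead_days_max = 72,
                       median_survival_months = 7.37,
                       censor_dropout_rate = 0.033,
                       background_death_hazard = 0.01,
                       transfer_rate = 0.03,
                       visit_rate_per_year = 1.2,
                       registration_lookback_days = 3650,
                       templates = default_templates(),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$study_start <- as_date(study_start)
  cfg$study_end <- as_date(study_end)
  probs <- c("p_code_lung_given_sclc", "p_code_scc_given_sclc",
             "p_code_lung_given_nsclc", "p_code_scc_given_other",
             "p_cross_code", "p_text_sclc", "p_text_non", "p_text_lung",
             "p_text_lung_given_other", "p_ambiguous_nsclc",
             "p_ambiguous_sclc", "p_symptom_before", "censor_dropout_rate",
             "transfer_rate")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_param("'", nm, "' must be a probability in [0, 1]")
    }
  }
  if (cfg$p_code_lung_given_sclc + cfg$p_code_scc_given_sclc > 1 + 1e-12) {
    stop_param("'p_code_lung_given_sclc' + 'p_code_scc_given_sclc' exceeds 1")
  }
  for (nm in c("annual_sclc_hazard", "background_death_hazard",
               "visit_rate_per_year")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop_param("'", nm, "' must be a non-negative rate")
    }
  }
  for (nm in c("nsclc_to_sclc_ratio", "other_lung_to_sclc_ratio",
               "median_survival_months")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop_param("'", nm, "' must be positive")
    }
  }
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    stop_param("'n_patients' must be at least 1")
  }
  if (cfg$study_start >= cfg$study_end) {
    stop_param("'study_start' must precede 'study_end'")
  }
  if (cfg$symptom_lead_days_max < 1) {
    stop_param("'symptom_lead_days_max' must be at least 1 day")
  }
  if (!all(c("sclc", "non", "ambiguous", "lung") %in% names(cfg$templates))) {
    stop_param("'templates' must provide sclc, non, ambiguous and lung sets")
  }
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

runi_int <- function(n, lo, hi) {
  # uniform integer draw on lo..hi, vectorised over lo/hi
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

#' Generate a synthetic EHR bundle
#'
#' Simulates a population of registered patients, assigns true disease by
#' competing exponential onset clocks running over each patient's at-risk
#' time inside the study window, and writes the coded events, free-text
#' comments, prescriptions and deaths that the configured recording
#' probabilities imply. Identical configurations (including the seed)
#' produce identical bundles.
#'
#' @param config A [sim_config()].
#' @return An [ehr_bundle()] with ground-truth labels.
#' @examples
#' b <- generate_bundle(sim_config(n_patients = 500, seed = 42))
#' b
#' @export
generate_bundle <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_param("'config' must be a sim_config object")
  }
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  d0 <- cfg$study_start
  d1 <- cfg$study_end
  total_days <- days_between(d1, d0)
  horizon <- d1 + 455L  # one year of mortality follow-up plus backdating slack

  ## ---- patients -----------------------------------------------------------
  patient_id <- seq_len(n)
  sex <- c("M", "F")[1L + (stats::runif(n) < 0.487)]
  # ages 20-84 at study start so entry ages span the 18-89 eligibility band
  birth_date <- d0 - floor(stats::runif(n, 20 * 365.25, 85 * 365.25))
  registration_start <- d0 + runi_int(n, -cfg$registration_lookback_days,
                                      max(total_days - 1095L, 0L))
  first_rx_delay <- runi_int(n, 0L, 180L)
  first_rx_date <- registration_start + first_rx_delay

  at_risk_start <- pmax(d0, registration_start + 730L, first_rx_date + 730L)
  age_ars <- age_at(birth_date, at_risk_start)
  in_play <- at_risk_start < d1 & age_ars >= 18 & age_ars <= 89
  span_years <- pmax(days_between(d1, at_risk_start), 0L) / DAYS_PER_YEAR

  ## ---- disease assignment: competing exponential clocks -------------------
  h_s <- cfg$annual_sclc_hazard
  h_n <- h_s * cfg$nsclc_to_sclc_ratio
  h_o <- h_s * cfg$other_lung_to_sclc_ratio
  rexp_safe <- function(rate) if (rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  t_s <- rexp_safe(h_s)
  t_n <- rexp_safe(h_n)
  t_o <- rexp_safe(h_o)
  t_bg <- rexp_safe(cfg$background_death_hazard)
  t_first <- pmin(t_s, t_n, t_o)
  is_case <- in_play & t_first <= span_years & t_first < t_bg
  disease <- rep("NONE", n)
  disease[is_case & t_first == t_s] <- "SCLC"
  disease[is_case & t_first == t_n] <- "NSCLC"
  disease[is_case & t_first == t_o] <- "OTHER_LUNG"
  onset <- as.Date(rep(NA, n))
  onset[is_case] <- at_risk_start[is_case] +
    floor(t_first[is_case] * DAYS_PER_YEAR)

  ## ---- per-case recording behaviour ---------------------------------------
  ci <- which(is_case)
  m <- length(ci)
  index_type <- rep(NA_character_, n)  # "lung", "scc" or NA (never coded)
  if (m) {
    u <- stats::runif(m)
    dz <- disease[ci]
    it <- rep(NA_character_, m)
    sel <- dz == "SCLC"
    it[sel & u < cfg$p_code_lung_given_sclc] <- "lung"
    it[sel & u >= cfg$p_code_lung_given_sclc &
         u < cfg$p_code_lung_given_sclc + cfg$p_code_scc_given_sclc] <- "scc"
    sel <- dz == "NSCLC"
    it[sel & u < cfg$p_code_lung_given_nsclc] <- "lung"
    sel <- dz == "OTHER_LUNG"
    it[sel & u < cfg$p_code_scc_given_other] <- "scc"
    index_type[ci] <- it
  }

  has_symptom <- is_case & stats::runif(n) < cfg$p_symptom_before
  lead_days <- integer(n)
  lead_days[has_symptom] <- runi_int(sum(has_symptom), 1L,
                                     cfg$symptom_lead_days_max)

  ## ---- deaths and record ends ---------------------------------------------
  # cancer survival: exponential in months, log-hazard shifted by sex and age
  surv_months <- rep(Inf, n)
  if (m) {
    base_rate <- log(2) / cfg$median_survival_months
    med_factor <- ifelse(disease[ci] == "SCLC", 1, 2)  # non-SCLC less aggressive
    rate <- base_rate / med_factor *
      exp(0.35 * (sex[ci] == "M") + 0.025 * (age_at(birth_date[ci], onset[ci]) - 68))
    surv_months[ci] <- stats::rexp(m, rate)
  }
  cancer_death <- as.Date(rep(NA, n))
  cancer_death[ci] <- onset[ci] + pmax(ceiling(surv_months[ci] * DAYS_PER_MONTH), 1)
  bg_death <- at_risk_start + ceiling(pmin(t_bg, 200) * DAYS_PER_YEAR)
  true_death <- pmin(bg_death, cancer_death, na.rm = TRUE)

  # diagnosis must be recorded before death: cap the lead time
  days_to_death <- days_between(true_death, onset)
  lead_days[ci] <- pmin(lead_days[ci], pmax(days_to_death[ci] - 1L, 0L))
  index_date <- onset + lead_days

  # independent transfer out of the practice (excluded from any cohort)
  transfer <- stats::runif(n) < cfg$transfer_rate
  reg_span <- pmax(days_between(pmin(horizon, true_death), registration_start), 101L)
  transfer_date <- as.Date(rep(NA, n))
  transfer_date[transfer] <- registration_start[transfer] +
    runi_int(sum(transfer), 100L, reg_span[transfer])
  transfer <- transfer & (is.na(true_death) | transfer_date < true_death)

  # mortality-follow-up dropout: the practice's data feed stops shortly
  # after the diagnosis; status stays "permanent", later death unrecorded
  dropout <- is_case & !is.na(index_type) & !transfer &
    stats::runif(n) < cfg$censor_dropout_rate
  datastop <- as.Date(rep(NA, n))
  datastop[dropout] <- index_date[dropout] + runi_int(sum(dropout), 30L, 360L)
  dropout <- dropout & (is.na(true_death) | datastop < true_death)

  registration_status <- rep("permanent", n)
  registration_end <- as.Date(rep(NA, n))
  death_date <- as.Date(rep(NA, n))
  died <- !transfer & !dropout & !is.na(true_death) & true_death <= horizon
  registration_status[died] <- "died"
  registration_end[died] <- true_death[died]
  death_date[died] <- true_death[died]
  registration_status[transfer] <- "transferred"
  registration_end[transfer] <- transfer_date[transfer]
  registration_end[dropout] <- datastop[dropout]

  record_end <- registration_end
  record_end[is.na(record_end)] <- horizon

  patients <- data.table::data.table(
    patient_id = patient_id, sex = sex, birth_date = birth_date,
    registration_start = registration_start,
    registration_status = registration_status,
    registration_end = registration_end, death_date = death_date
  )

  ## ---- events -------------------------------------------------------------
  codes <- default_codes()
  lung_codes <- codes_of(codes, "lung_cancer")
  scc_codes <- codes_of(codes, "scc")
  symptom_codes <- codes_of(codes, "symptom")
  proc_codes <- codes_of(codes, "procedure")
  comorb <- codes[codes$category == "comorbidity", ]

  ev_list <- list()
  add_events <- function(pid, date, code, text = NA_character_) {
    keep <- !is.na(date) & date >= registration_start[pid] & date <= record_end[pid]
    if (!any(keep)) return(invisible())
    ev_list[[length(ev_list) + 1L]] <<- data.table::data.table(
      patient_id = pid[keep], event_date = date[keep],
      code = rep_len(code, length(pid))[keep],
      free_text = rep_len(text, length(pid))[keep])
  }

  # routine visits
  span_reg <- pmax(days_between(record_end, registration_start), 1L)
  n_visits <- stats::rpois(n, cfg$visit_rate_per_year * span_reg / DAYS_PER_YEAR)
  vp <- rep(patient_id, n_visits)
  vdate <- registration_start[vp] +
    floor(stats::runif(length(vp)) * span_reg[vp])
  add_events(vp, vdate, "VISIT")

  # lifestyle records shortly after registration
  smoking <- sample(c("SMOK_NON", "SMOK_CURR", "SMOK_FORMER"), n, TRUE,
                    prob = c(0.30, 0.40, 0.30))
  bmi <- sample(c("BMI_15_19", "BMI_20_24", "BMI_25_29", "BMI_30PLUS"), n,
                TRUE, prob = c(0.06, 0.37, 0.33, 0.24))
  alco <- sample(c("ALC_NONE", "ALC_1_9", "ALC_10_20", "ALC_21_41",
                   "ALC_42PLUS"), n, TRUE,
                 prob = c(0.25, 0.45, 0.18, 0.08, 0.04))
  has_life <- stats::runif(n) < 0.95
  ldate <- registration_start + runi_int(n, 0L, 365L)
  add_events(patient_id[has_life], ldate[has_life], smoking[has_life])
  add_events(patient_id[has_life], ldate[has_life] + 1L, bmi[has_life])
  add_events(patient_id[has_life], ldate[has_life] + 2L, alco[has_life])

  # comorbidity history
  com_p <- c(mi = 0.08, ischaemic_stroke = 0.05, hypertension = 0.35,
             depression = 0.25, asthma = 0.20, copd = 0.15)
  for (k in seq_len(nrow(comorb))) {
    has <- stats::runif(n) < com_p[[comorb$label[k]]]
    cdate <- registration_start + floor(stats::runif(n) * span_reg)
    add_events(patient_id[has], cdate[has], comorb$code[k])
  }

  if (m) {
    # symptom at onset, an imaging procedure during the lead time
    si <- ci[has_symptom[ci]]
    add_events(si, onset[si],
               sample(symptom_codes, length(si), TRUE))
    pi_ <- si[stats::runif(length(si)) < 0.7]
    pdate <- onset[pi_] + floor(stats::runif(length(pi_)) * lead_days[pi_])
    add_events(pi_, pdate, sample(proc_codes, length(pi_), TRUE,
                                  prob = c(0.55, 0.2, 0.15, 0.1)))

    # index code
    coded <- ci[!is.na(index_type[ci])]
    icode <- ifelse(index_type[coded] == "lung",
                    sample(lung_codes, length(coded), TRUE),
                    sample(scc_codes, length(coded), TRUE))
    add_events(coded, index_date[coded], icode)

    # cross code within +/-90 days (SCLC only; clamp keeps it in-window
    # and inside the record)
    sclc_coded <- coded[disease[coded] == "SCLC"]
    xi <- sclc_coded[stats::runif(length(sclc_coded)) < cfg$p_cross_code]
    xdate <- index_date[xi] + runi_int(length(xi), -90L, 90L)
    xdate <- pmin(pmax(xdate, registration_start[xi]), record_end[xi])
    xcode <- ifelse(index_type[xi] == "lung",
                    sample(scc_codes, length(xi), TRUE),
                    sample(lung_codes, length(xi), TRUE))
    add_events(xi, xdate, xcode)

    # free-text comment in the [-30, +90] window around the index code
    tpl <- cfg$templates
    pick <- function(set, k) sample(tpl[[set]], k, replace = TRUE)
    u_amb <- stats::runif(n)
    u_txt <- stats::runif(n)
    note_for <- function(idx, set) {
      if (!length(idx)) return(invisible())
      ndate <- index_date[idx] + runi_int(length(idx), -30L, 90L)
      ndate <- pmin(pmax(ndate, registration_start[idx]), record_end[idx])
      add_events(idx, ndate, "NOTE", pick(set, length(idx)))
    }
    g1_sclc <- coded[disease[coded] == "SCLC" & index_type[coded] == "lung"]
    note_for(g1_sclc[u_amb[g1_sclc] < cfg$p_ambiguous_sclc], "ambiguous")
    note_for(g1_sclc[u_amb[g1_sclc] >= cfg$p_ambiguous_sclc &
                       u_txt[g1_sclc] < cfg$p_text_sclc], "sclc")
    g2_sclc <- coded[disease[coded] == "SCLC" & index_type[coded] == "scc"]
    note_for(g2_sclc[u_txt[g2_sclc] < cfg$p_text_lung], "lung")
    g1_nsclc <- coded[disease[coded] == "NSCLC"]
    note_for(g1_nsclc[u_amb[g1_nsclc] < cfg$p_ambiguous_nsclc], "ambiguous")
    note_for(g1_nsclc[u_amb[g1_nsclc] >= cfg$p_ambiguous_nsclc &
                        u_txt[g1_nsclc] < cfg$p_text_non], "non")
    g2_other <- coded[disease[coded] == "OTHER_LUNG"]
    note_for(g2_other[u_txt[g2_other] < cfg$p_text_lung_given_other], "lung")
  }

  if (length(ev_list)) {
    events <- data.table::rbindlist(ev_list)
  } else {
    events <- data.table::data.table(patient_id = integer(),
                                     event_date = as.Date(character()),
                                     code = character(),
                                     free_text = character())
  }
  data.table::setorder(events, patient_id, event_date, code)

  ## ---- prescriptions ------------------------------------------------------
  classes <- c("beta2_agonist", "oral_corticosteroid", "inhaled_steroid",
               "antiplatelet", "nsaid", "opioid", "ppi", "h2ra", "other")
  rx_first <- data.table::data.table(
    patient_id = patient_id, issue_date = first_rx_date,
    drug_class = sample(classes, n, TRUE), supply_days = 28L)
  n_rx <- stats::rpois(n, 0.6 * span_reg / DAYS_PER_YEAR)
  rp <- rep(patient_id, n_rx)
  rx_rep <- data.table::data.table(
    patient_id = rp,
    issue_date = registration_start[rp] +
      floor(stats::runif(length(rp)) * span_reg[rp]),
    drug_class = sample(classes, length(rp), TRUE),
    supply_days = sample(c(14L, 28L, 56L), length(rp), TRUE))
  rx_case <- NULL
  if (m) {
    coded <- ci[!is.na(index_type[ci])]
    op <- coded[stats::runif(length(coded)) < 0.55]
    rx_case <- data.table::data.table(
      patient_id = op,
      issue_date = pmax(index_date[op] - runi_int(length(op), 0L, 300L),
                        registration_start[op]),
      drug_class = "opioid", supply_days = 28L)
  }
  rx <- data.table::rbindlist(list(rx_first, rx_rep, rx_case))
  rx <- rx[issue_date >= registration_start[patient_id] &
             issue_date <= record_end[patient_id]]
  data.table::setorder(rx, patient_id, issue_date)

  ## ---- truth --------------------------------------------------------------
  stage <- rep("unknown", n)
  if (m) {
    s_ci <- ci[disease[ci] == "SCLC"]
    stage[s_ci] <- sample(c("limited", "extensive", "unknown"),
                          length(s_ci), TRUE, prob = c(0.113, 0.522, 0.365))
  }
  truth <- data.table::data.table(
    patient_id = patient_id, true_disease = disease,
    true_onset_date = onset, true_stage = stage,
    true_death_date = true_death)

  ehr_bundle(patients, events, rx, truth, validate = FALSE)
}
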