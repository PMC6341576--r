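# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except the package's own extdata.

D <- function(x) as.Date(x)

# A hand-built bundle: flexible constructor with per-table defaults.
mini_bundle <- function(patients, events = NULL, prescriptions = NULL,
                        truth = NULL, validate = TRUE) {
  ids <- patients$patient_id
  if (is.null(events)) {
    events <- data.frame(patient_id = integer(), event_date = D(character()),
                         code = character(), free_text = character())
  }
  if (is.null(prescriptions)) {
    prescriptions <- data.frame(patient_id = ids,
                                issue_date = D(patients$registration_start),
                                drug_class = "other", supply_days = 28L)
  }
  if (is.null(truth)) {
    truth <- data.frame(patient_id = ids, true_disease = "NONE",
                        true_onset_date = D(NA), true_stage = "unknown",
                        true_death_date = D(NA))
  }
  ehr_bundle(patients, events, prescriptions, truth, validate = validate)
}

# One long-registered, always-eligible patient.
mk_patient <- function(id = 1L, sex = "M", birth = "1950-06-15",
                       reg = "1995-01-01", status = "permanent",
                       reg_end = NA, death = NA) {
  data.frame(patient_id = id, sex = sex, birth_date = D(birth),
             registration_start = D(reg), registration_status = status,
             registration_end = D(reg_end), death_date = D(death))
}

mk_events <- function(id, dates, codes, text = NA_character_) {
  data.frame(patient_id = id, event_date = D(dates), code = codes,
             free_text = text)
}

# A visit each year so the encounter criterion is always met.
annual_visits <- function(id, from = "1995-06-01", to = "2014-06-01") {
  dates <- seq(D(from), D(to), by = "year")
  mk_events(id, format(dates), "VISIT")
}

small_sim <- function(n = 2000, seed = 1, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}
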