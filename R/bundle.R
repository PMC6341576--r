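#' Linked EHR extract tables
#'
#' An `ehr_bundle` holds the four linked tables every pipeline stage
#' consumes, mirroring the layout of a primary-care database extract:
#'
#' * `patients`: one row per registered patient — `patient_id`, `sex`
#'   (`"M"`/`"F"`), `birth_date`, `registration_start`,
#'   `registration_status` (`"permanent"`, `"died"`, `"transferred"`),
#'   `registration_end` (`NA` while permanently registered), `death_date`
#'   (`NA` unless status is `"died"`).
#' * `events`: dated coded clinical entries — `patient_id`, `event_date`,
#'   `code`, and an optional `free_text` comment (`NA` when absent).
#' * `prescriptions`: `patient_id`, `issue_date`, `drug_class`,
#'   `supply_days` (>= 1).
#' * `truth`: simulation ground truth — `patient_id`, `true_disease`
#'   (`"SCLC"`, `"NSCLC"`, `"OTHER_LUNG"`, `"NONE"`), `true_onset_date`,
#'   `true_stage` (`"limited"`, `"extensive"`, `"unknown"`),
#'   `true_death_date`. Absent (0 rows) when the bundle comes from real
#'   data.
#'
#' @param patients,events,prescriptions,truth Data frames with the columns
#'   above; date columns may be `Date` or ISO-8601 strings.
#' @param validate Check invariants (linkage, date ordering, events inside
#'   registration)? Default `TRUE`.
#' @return An object of class `ehr_bundle` (a named list of data.tables).
#' @seealso [generate_bundle()], [read_bundle()], [write_bundle()]
#' @export
ehr_bundle <- function(patients, events, prescriptions,
                       truth = NULL, validate = TRUE) {
  req <- list(
    patients = c("patient_id", "sex", "birth_date", "registration_start",
                 "registration_status", "registration_end", "death_date"),
    events = c("patient_id", "event_date", "code", "free_text"),
    prescriptions = c("patient_id", "issue_date", "drug_class", "supply_days"),
    truth = c("patient_id", "true_disease", "true_onset_date", "true_stage",
              "true_death_date")
  )
  if (is.null(truth)) {
    truth <- data.frame(patient_id = integer(), true_disease = character(),
                        true_onset_date = as.Date(character()),
                        true_stage = character(),
                        true_death_date = as.Date(character()))
  }
  tabs <- list(patients = patients, events = events,
               prescriptions = prescriptions, truth = truth)
  for (nm in names(tabs)) {
    missing_cols <- setdiff(req[[nm]], names(tabs[[nm]]))
    if (length(missing_cols)) {
      stop_format("table '", nm, "' is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
    }
    tabs[[nm]] <- data.table::as.data.table(tabs[[nm]])[, req[[nm]], with = FALSE]
  }
  date_cols <- list(
    patients = c("birth_date", "registration_start", "registration_end",
                 "death_date"),
    events = "event_date", prescriptions = "issue_date",
    truth = c("true_onset_date", "true_death_date")
  )
  for (nm in names(date_cols)) {
    for (cc in date_cols[[nm]]) {
      data.table::set(tabs[[nm]], j = cc, value = as_date(tabs[[nm]][[cc]]))
    }
  }
  chr_cols <- list(patients = c("sex", "registration_status"),
                   events = c("code", "free_text"),
                   prescriptions = "drug_class",
                   truth = c("true_disease", "true_stage"))
  for (nm in names(chr_cols)) {
    for (cc in chr_cols[[nm]]) {
      data.table::set(tabs[[nm]], j = cc, value = as.character(tabs[[nm]][[cc]]))
    }
  }
  data.table::set(tabs$prescriptions, j = "supply_days",
                  value = as.integer(tabs$prescriptions$supply_days))
  bundle <- structure(tabs, class = "ehr_bundle")
  if (validate) validate_bundle(bundle)
  bundle
}

#' Check the invariants of an EHR bundle
#'
#' Verifies linkage (every event/prescription/truth row refers to a known
#' patient), registration-date ordering, death-date/status consistency,
#' that clinical events fall inside their patient's registration interval,
#' and that truth onset dates are present exactly for diseased patients.
#' Errors on the first violation found.
#'
#' @param bundle An [ehr_bundle()].
#' @return The bundle, invisibly, if all invariants hold.
#' @export
validate_bundle <- function(bundle) {
  p <- bundle$patients
  if (anyDuplicated(p$patient_id)) {
    stop_format("duplicate patient_id in patients table")
  }
  bad <- !is.na(p$registration_end) & p$registration_end < p$registration_start
  if (any(bad)) stop_format("registration_end precedes registration_start")
  died <- p$registration_status == "died"
  if (any(died & is.na(p$death_date)) || any(!died & !is.na(p$death_date))) {
    stop_format("death_date must be present iff registration_status is 'died'")
  }
  for (nm in c("events", "prescriptions", "truth")) {
    orphan <- setdiff(bundle[[nm]]$patient_id, p$patient_id)
    if (length(orphan)) {
      stop_linkage("table '", nm, "' refers to unknown patient_id(s), e.g. ",
                   orphan[1])
    }
  }
  ev <- merge(bundle$events,
              p[, c("patient_id", "registration_start", "registration_end")],
              by = "patient_id")
  out <- ev$event_date < ev$registration_start |
    (!is.na(ev$registration_end) & ev$event_date > ev$registration_end)
  if (any(out)) {
    stop_format("clinical event outside patient registration interval ",
                "(patient ", ev$patient_id[which(out)[1]], ")")
  }
  tr <- bundle$truth
  if (nrow(tr)) {
    need_onset <- tr$true_disease != "NONE"
    if (any(need_onset & is.na(tr$true_onset_date)) ||
        any(!need_onset & !is.na(tr$true_onset_date))) {
      stop_format("true_onset_date must be present iff true_disease != NONE")
    }
  }
  if (any(bundle$prescriptions$supply_days < 1)) {
    stop_format("prescription supply_days must be >= 1")
  }
  invisible(bundle)
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>\n")
  cat(sprintf("  patients:      %7d\n", nrow(x$patients)))
  cat(sprintf("  events:        %7d  (%d with free text)\n",
              nrow(x$events), sum(!is.na(x$events$free_text))))
  cat(sprintf("  prescriptions: %7d\n", nrow(x$prescriptions)))
  if (nrow(x$truth)) {
    tab <- table(x$truth$true_disease)
    cat("  truth labels:  ",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  } else {
    cat("  truth labels:   none (real-data bundle)\n")
  }
  invisible(x)
}

bundle_files <- c(patients = "patients.csv", events = "events.csv",
                  prescriptions = "prescriptions.csv", truth = "truth.csv")

#' Write an EHR bundle to a directory of CSV tables
#'
#' Four RFC-4180 CSV files (`patients.csv`, `events.csv`,
#' `prescriptions.csv`, `truth.csv`) with ISO-8601 dates and UTF-8 text.
#'
#' @param bundle An [ehr_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle_files)) {
    utils::write.csv(as.data.frame(bundle[[nm]]),
                     file.path(dir, bundle_files[[nm]]),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read an EHR bundle from a directory of CSV tables
#'
#' @param dir Directory containing the four CSV tables written by
#'   [write_bundle()].
#' @param validate Check bundle invariants on load? Default `TRUE`.
#' @return An [ehr_bundle()].
#' @export
read_bundle <- function(dir, validate = TRUE) {
  paths <- file.path(dir, bundle_files)
  missing_file <- !file.exists(paths)
  if (any(missing_file)) {
    stop_format("bundle directory is missing table file(s): ",
                paste(bundle_files[missing_file], collapse = ", "))
  }
  read1 <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                    fileEncoding = "UTF-8")
  }
  tabs <- lapply(paths, read1)
  names(tabs) <- names(bundle_files)
  # read.csv drops column typing for all-NA columns; coerced in ehr_bundle()
  ehr_bundle(tabs$patients, tabs$events, tabs$prescriptions, tabs$truth,
             validate = validate)
}
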