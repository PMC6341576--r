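# End-to-end orchestration: simulate (optional) -> cohort -> ascertain ->
# validate -> epi statistics, with file outputs and a run log.

#' Run the ascertainment chain on a bundle (no file output)
#'
#' Cohort eligibility, index-code detection, cross-code confirmation,
#' free-text window flags and stratum classification in one call.
#'
#' @param bundle An [ehr_bundle()].
#' @param codelist A [code_list()].
#' @param patterns A [pattern_set()].
#' @param study_start,study_end Study window.
#' @param cross_code_days Cross-code window half-width (days).
#' @param text_lo,text_hi Text-search window offsets (days, relative to the
#'   index date).
#' @param backdate_lookback Backdating lookback (days).
#' @return List with `followups`, `assignments`, `cross_flags`,
#'   `text_flags`, `classifications` (including `final_event_date`) and
#'   `counts` (an `sclc_step_counts` without extrapolation).
#' @export
ascertain_sclc <- function(bundle, codelist = default_codes(),
                           patterns = default_patterns(),
                           study_start = "2000-01-01",
                           study_end = "2014-12-31",
                           cross_code_days = 90L, text_lo = -30L,
                           text_hi = 90L, backdate_lookback = 90L) {
  followups <- eligible_cohort(bundle, codelist, study_start, study_end)
  assignments <- detect_index(bundle, followups, codelist)
  cross_flags <- cross_code(assignments, bundle, codelist, cross_code_days)
  non_cross <- assignments[!cross_flags$cross_code[
    match(assignments$patient_id, cross_flags$patient_id)], ]
  text_flags <- window_flags_all(
    bundle$events,
    data.frame(patient_id = non_cross$patient_id,
               anchor_date = non_cross$index_date),
    lo_days = text_lo, hi_days = text_hi, patterns = patterns)
  classifications <- classify_cases(assignments, cross_flags, text_flags)
  classifications <- backdate_all(bundle, classifications, codelist,
                                  backdate_lookback)
  list(followups = followups, assignments = assignments,
       cross_flags = cross_flags, text_flags = text_flags,
       classifications = classifications,
       counts = step_counts(classifications))
}

#' Pipeline run configuration
#'
#' @param bundle_dir Directory with an existing bundle (ignored when `sim`
#'   is given).
#' @param sim A [sim_config()] to generate the bundle, or `NULL`.
#' @param codes_path,patterns_path Optional CSV paths; package defaults
#'   otherwise.
#' @param study_start,study_end Study window.
#' @param cross_code_days,text_lo,text_hi,backdate_lookback Window
#'   parameters (days).
#' @param sample_sizes Review sample sizes per text stratum (named:
#'   `sclc_only`, `non_only`, `both`, `lung`); clamped to stratum counts.
#' @param ppv_sample PPV review sample sizes (named `group1`, `group2`),
#'   drawn from the `text_sclc_only` and `text_lung` strata.
#' @param review_error_rate Verdict flip probability in simulated review.
#' @param seed Integer seed for all sampling in the run.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @return A `run_config` list.
#' @export
run_config <- function(bundle_dir = NULL, sim = NULL, codes_path = NULL,
                       patterns_path = NULL,
                       study_start = "2000-01-01", study_end = "2014-12-31",
                       cross_code_days = 90L, text_lo = -30L, text_hi = 90L,
                       backdate_lookback = 90L,
                       sample_sizes = c(sclc_only = 18, non_only = 18,
                                        both = 20, lung = 25),
                       ppv_sample = c(group1 = 300, group2 = 100),
                       review_error_rate = 0, seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$bundle_dir) && is.null(cfg$sim)) {
    stop_config("either 'bundle_dir' or 'sim' must be provided")
  }
  if (!is.null(cfg$sim) && !inherits(cfg$sim, "sim_config")) {
    stop_config("'sim' must be a sim_config object")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' The file holds any subset of the [run_config()] arguments; a `sim` block
#' is passed to [sim_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("the 'yaml' package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  for (nm in c("sample_sizes", "ppv_sample")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(run_config, raw)
}

#' Execute the full pipeline
#'
#' Runs (optional) simulation, cohort construction, the four-step
#' ascertainment, simulated validation, and the epidemiological outputs,
#' writing `followups.csv`, `classifications.csv`, `step_counts.json`,
#' `validation_report.json`, `table1.csv`, `table3.csv`, `km_curve.csv`
#' and `run_log.txt` to `out_dir` when one is configured. Identical
#' configurations (including seeds) give identical outputs. An internal
#' consistency check re-derives every count in `step_counts` from the
#' classification table and errors on mismatch.
#'
#' @param config A [run_config()].
#' @return Object of class `sclc_run`: the inputs, intermediate tables,
#'   `counts` (extrapolated), `rates`, `validation` (PPV estimates and
#'   exclusion tally), `incidence`, `mortality`, `km`, `baseline`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("seed: ", config$seed)

  bundle <- if (!is.null(config$sim)) {
    note("stage simulate: n_patients=", config$sim$n_patients,
         " seed=", config$sim$seed)
    generate_bundle(config$sim)
  } else {
    note("stage load: ", config$bundle_dir)
    read_bundle(config$bundle_dir)
  }
  codelist <- if (is.null(config$codes_path)) default_codes() else
    load_codelist(config$codes_path)
  patterns <- if (is.null(config$patterns_path)) default_patterns() else
    load_patterns(config$patterns_path)

  asc <- ascertain_sclc(bundle, codelist, patterns,
                        config$study_start, config$study_end,
                        config$cross_code_days, config$text_lo,
                        config$text_hi, config$backdate_lookback)
  note("stage cohort: ", nrow(asc$followups), " eligible patients, ",
       sprintf("%.1f", total_person_years(asc$followups)), " person-years")
  note("stage ascertain: group1=", asc$counts$n_group1,
       " group2=", asc$counts$n_group2,
       " cross1=", asc$counts$n_cross1, " cross2=", asc$counts$n_cross2,
       " sclc_only=", asc$counts$n_text_sclc_only,
       " non_only=", asc$counts$n_text_non_only,
       " both=", asc$counts$n_text_both,
       " lung=", asc$counts$n_text_lung)

  cl <- asc$classifications
  have_truth <- nrow(bundle$truth) > 0

  ## ---- step 4: stratum review and confirmation rates ----------------------
  strata_map <- c(sclc_only = "text_sclc_only", non_only = "text_non_only",
                  both = "text_both", lung = "text_lung")
  outcomes <- list()
  rates <- c(sclc_only = 1, both = 0, lung = 1)
  if (have_truth) {
    for (k in names(strata_map)) {
      st <- strata_map[[k]]
      avail <- sum(cl$stratum == st)
      size <- min(config$sample_sizes[[k]], avail)
      if (size < config$sample_sizes[[k]]) {
        note("stratum ", st, ": sample clamped to stratum size ", avail)
      }
      if (size == 0) next
      ids <- draw_review_sample(cl, st, size, seed = config$seed + match(k, names(strata_map)))
      outcomes[[k]] <- review_cases(ids, bundle, asc$followups,
                                    config$review_error_rate,
                                    seed = config$seed + 100 + match(k, names(strata_map)))
    }
    for (k in c("sclc_only", "both", "lung")) {
      if (!is.null(outcomes[[k]])) {
        rates[[k]] <- confirmation_rates(outcomes[k])[[k]]
      }
    }
    note("stage validate: confirmation rates ",
         paste(names(rates), sprintf("%.3f", rates), sep = "=",
               collapse = " "))
  } else {
    note("stage validate: no truth labels; using assumed rates 1/0/1")
  }
  counts <- extrapolate_cases(asc$counts, as.list(rates))
  note("expected cases: total=", counts$expected_cases_total,
       " final=", counts$expected_cases_final,
       " ambiguous_term=", counts$term_both)

  ## ---- PPV validation sample ----------------------------------------------
  validation <- NULL
  if (have_truth) {
    n1 <- min(config$ppv_sample[["group1"]], sum(cl$stratum == "text_sclc_only"))
    n2 <- min(config$ppv_sample[["group2"]], sum(cl$stratum == "text_lung"))
    ids1 <- draw_review_sample(cl, "text_sclc_only", n1,
                               seed = config$seed + 11)
    ids2 <- draw_review_sample(cl, "text_lung", n2, seed = config$seed + 12)
    o1 <- review_cases(ids1, bundle, asc$followups,
                       config$review_error_rate, seed = config$seed + 111)
    o2 <- review_cases(ids2, bundle, asc$followups,
                       config$review_error_rate, seed = config$seed + 112)
    both <- rbind(o1, o2)
    if (nrow(both)) validation <- list(
      ppv_overall = ppv_estimate(both),
      ppv_group1 = if (nrow(o1)) ppv_estimate(o1) else NULL,
      ppv_group2 = if (nrow(o2)) ppv_estimate(o2) else NULL,
      exclusions = exclusion_tally(both),
      outcomes = both)
    note("stage ppv: overall ", validation$ppv_overall$n_confirmed, "/",
         validation$ppv_overall$n_reviewed)
  }

  ## ---- epi outputs ---------------------------------------------------------
  person_years <- total_person_years(asc$followups)
  incidence <- incidence_rate(counts$expected_cases_final, person_years)
  cases <- cl[cl$is_expected_case, ]
  mortality <- NULL
  km <- NULL
  baseline <- NULL
  if (nrow(cases)) {
    rec <- survival_records(bundle, cases)
    mortality <- mortality_summary(rec)
    km <- km_estimate(rec)
    baseline <- baseline_table(bundle, cases, codelist)
    note("stage epistats: ", nrow(rec), " cases in mortality analysis, ",
         sum(rec$event), " deaths")
  }

  run <- structure(list(config = config, bundle = bundle,
                        codelist = codelist, patterns = patterns,
                        followups = asc$followups,
                        classifications = cl, counts = counts,
                        rates = rates, validation = validation,
                        person_years = person_years, incidence = incidence,
                        mortality = mortality, km = km, baseline = baseline,
                        log = log_lines),
                   class = "sclc_run")
  check_run_consistency(run)
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# Every count in the step-counts object must be re-derivable from the
# classification table.
check_run_consistency <- function(run) {
  rec <- step_counts(run$classifications)
  for (nm in names(rec)) {
    if (!identical(as.numeric(rec[[nm]]), as.numeric(run$counts[[nm]]))) {
      stop("internal consistency check failed for count '", nm, "'")
    }
  }
  ex <- extrapolate_cases(rec, run$counts$rates)
  if (ex$expected_cases_final != run$counts$expected_cases_final) {
    stop("internal consistency check failed for expected_cases_final")
  }
  invisible(TRUE)
}

step_counts_json <- function(counts) {
  out <- lapply(unclass(counts), function(x) {
    if (is.list(x)) lapply(x, as.numeric) else as.numeric(x)
  })
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) {
    utils::write.csv(as.data.frame(x), file.path(out_dir, f),
                     row.names = FALSE, na = "")
  }
  wcsv(run$followups, "followups.csv")
  wcsv(run$classifications, "classifications.csv")
  writeLines(step_counts_json(run$counts),
             file.path(out_dir, "step_counts.json"))
  if (!is.null(run$validation)) {
    v <- run$validation
    as_list_ppv <- function(p) {
      if (is.null(p)) return(NULL)
      list(n_confirmed = p$n_confirmed, n_reviewed = p$n_reviewed,
           ppv = p$ppv, ci_low = p$ci_low, ci_high = p$ci_high)
    }
    report <- list(ppv_overall = as_list_ppv(v$ppv_overall),
                   ppv_group1 = as_list_ppv(v$ppv_group1),
                   ppv_group2 = as_list_ppv(v$ppv_group2),
                   confirmation_rates = as.list(run$rates),
                   exclusion_reasons = as.list(v$exclusions))
    jsonlite::write_json(report, file.path(out_dir, "validation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wcsv(v$outcomes, "review_outcomes.csv")
  }
  if (!is.null(run$baseline)) wcsv(run$baseline, "table1.csv")
  if (!is.null(run$mortality)) wcsv(run$mortality, "table3.csv")
  if (!is.null(run$km)) wcsv(as.data.frame(run$km), "km_curve.csv")
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.sclc_run <- function(x, ...) {
  cat("SCLC ascertainment pipeline run\n")
  cat(sprintf("  eligible cohort: %d patients, %.1f person-years\n",
              nrow(x$followups), x$person_years))
  print(x$counts)
  cat(sprintf("  incidence: %.2f per %s person-years (95%% CI %.2f-%.2f)\n",
              x$incidence$rate, format(x$incidence$scale, big.mark = ","),
              x$incidence$ci_low, x$incidence$ci_high))
  if (!is.null(x$validation)) print(x$validation$ppv_overall)
  if (!is.null(x$km)) print(x$km)
  invisible(x)
}
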