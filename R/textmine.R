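# Negation-aware free-text string search.
#
# Clinical free-text comments are scanned for lower-cased substrings. An
# SCLC-suggestive string counts as a positive mention only when it is not
# immediately preceded by a negation prefix ("non"), allowing at most one
# space or hyphen between prefix and string: "non small cell lung cancer"
# and "non-small cell ca" are negated, "biopsy: small cell lung cancer" is
# not. Matching is deliberately simple string search — no stemming, no
# tokenisation beyond separator handling — mirroring how such searches are
# run against primary-care free text in practice.

# Positions where `pattern` occurs in `text` at a word start (the preceding
# character is neither a letter nor a digit). The word-start rule stops
# "sclc" from firing inside "nsclc"; the abbreviation is handled by the
# negated-token list instead.
pattern_starts <- function(text, pattern) {
  hits <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  ok <- vapply(hits, function(s) {
    s == 1L || !grepl("[a-z0-9]", substr(text, s - 1L, s - 1L))
  }, logical(1))
  as.integer(hits[ok])
}

# Is the occurrence starting at `s` preceded (allowing <= 1 space/hyphen)
# by one of the negation prefixes?
is_negated_at <- function(text, s, prefixes) {
  head <- substr(text, 1L, s - 1L)
  # strip at most one trailing separator character
  head <- sub("[ -]$", "", head)
  for (p in prefixes) {
    n <- nchar(p)
    if (nchar(head) >= n && substr(head, nchar(head) - n + 1L, nchar(head)) == p) {
      # the prefix itself must start at a word boundary ("non", not "cannon")
      before <- nchar(head) - n
      if (before == 0L ||
          !grepl("[a-z0-9]", substr(head, before, before))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Scan one free-text comment for SCLC, negated-SCLC and lung-cancer strings
#'
#' Case-insensitive substring search returning three independent flags:
#' `has_sclc_text` — an SCLC-suggestive string occurs without an immediately
#' preceding negation prefix; `has_non_text` — an SCLC string occurs *with*
#' such a prefix, or a dedicated negated token (e.g. `"nsclc"`) occurs;
#' `has_lung_text` — a lung-cancer string occurs.
#'
#' @param text A single character string (may be empty or `NA`).
#' @param patterns A [pattern_set()].
#' @return Named logical vector
#'   `c(has_sclc_text, has_non_text, has_lung_text)`.
#' @examples
#' ps <- pattern_set("small cell lung cancer", "non", "lung cancer", "nsclc")
#' match_text("small cell lung cancer confirmed on biopsy", ps)
#' match_text("non small cell lung cancer", ps)
#' @export
match_text <- function(text, patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  flags <- c(has_sclc_text = FALSE, has_non_text = FALSE,
             has_lung_text = FALSE)
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(text)) {
    return(flags)
  }
  text <- tolower(text)
  for (pat in patterns$sclc_patterns) {
    for (s in pattern_starts(text, pat)) {
      if (is_negated_at(text, s, patterns$negation_prefixes)) {
        flags[["has_non_text"]] <- TRUE
      } else {
        flags[["has_sclc_text"]] <- TRUE
      }
    }
  }
  for (tok in patterns$negated_tokens) {
    if (length(pattern_starts(text, tok))) {
      flags[["has_non_text"]] <- TRUE
      break
    }
  }
  for (pat in patterns$lung_patterns) {
    if (length(pattern_starts(text, pat))) {
      flags[["has_lung_text"]] <- TRUE
      break
    }
  }
  flags
}

#' Combine text flags over a patient's comments in a window around an anchor
#'
#' Scans the `free_text` of all events dated within
#' `[anchor + lo_days, anchor + hi_days]` (both ends inclusive; defaults
#' reproduce the 30-days-before to 90-days-after search window around the
#' index code) and OR-combines the per-comment flags.
#'
#' @param events Data frame of one patient's events (`event_date`,
#'   `free_text`).
#' @param anchor_date The index-code date.
#' @param lo_days,hi_days Window offsets in days relative to the anchor;
#'   defaults -30 and +90.
#' @param patterns A [pattern_set()].
#' @return Named logical vector as for [match_text()].
#' @export
window_flags <- function(events, anchor_date, lo_days = -30L, hi_days = 90L,
                         patterns = default_patterns()) {
  stopifnot(!missing(anchor_date), lo_days <= hi_days)
  anchor_date <- as_date(anchor_date)
  off <- days_between(events$event_date, anchor_date)
  txt <- events$free_text[off >= lo_days & off <= hi_days]
  txt <- txt[!is.na(txt) & nzchar(txt)]
  flags <- c(has_sclc_text = FALSE, has_non_text = FALSE,
             has_lung_text = FALSE)
  for (t in txt) {
    flags <- flags | match_text(t, patterns)
    if (all(flags)) break
  }
  flags
}

# Vectorised variant used by the ascertainment stage: computes the three
# flags for many patients at once. `events` must contain patient_id,
# event_date, free_text; `anchors` maps patient_id -> anchor date.
window_flags_all <- function(events, anchors, lo_days = -30L, hi_days = 90L,
                             patterns = default_patterns()) {
  ev <- data.table::as.data.table(events)[!is.na(free_text) & nzchar(free_text)]
  an <- data.table::data.table(patient_id = anchors$patient_id,
                               anchor = as_date(anchors$anchor_date))
  ev <- merge(ev, an, by = "patient_id")
  off <- days_between(ev$event_date, ev$anchor)
  ev <- ev[off >= lo_days & off <= hi_days]
  # match each distinct comment once
  utxt <- unique(ev$free_text)
  m <- t(vapply(utxt, match_text, logical(3), patterns = patterns))
  idx <- match(ev$free_text, utxt)
  ev[, `:=`(has_sclc_text = m[idx, 1], has_non_text = m[idx, 2],
            has_lung_text = m[idx, 3])]
  out <- ev[, .(has_sclc_text = any(has_sclc_text),
                has_non_text = any(has_non_text),
                has_lung_text = any(has_lung_text)), by = patient_id]
  res <- data.table::data.table(patient_id = anchors$patient_id)
  res <- merge(res, out, by = "patient_id", all.x = TRUE)
  for (cc in c("has_sclc_text", "has_non_text", "has_lung_text")) {
    data.table::set(res, which(is.na(res[[cc]])), cc, FALSE)
  }
  res
}
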