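#' Clinical code lists
#'
#' A `code_list` is a data frame tagging each clinical code with a category.
#' Recognised categories: `lung_cancer`, `scc` (small cell cancer of
#' unspecified site), `symptom`, `procedure`, `surgery`, `terminal_care`,
#' `comorbidity`, `lifestyle`, `encounter`. The optional `label` column
#' carries the variable a comorbidity or lifestyle code contributes to
#' (e.g. `"smoking:current"`, `"copd"`).
#'
#' @param codes Data frame with columns `code`, `category` and optionally
#'   `label`.
#' @return A `code_list` data frame.
#' @export
code_list <- function(codes) {
  if (!all(c("code", "category") %in% names(codes))) {
    stop_format("code list needs columns 'code' and 'category'")
  }
  codes <- as.data.frame(codes, stringsAsFactors = FALSE)
  if (!nrow(codes)) stop_config("empty code list")
  if (is.null(codes$label)) codes$label <- NA_character_
  codes$label <- as.character(codes$label)
  codes <- unique(codes[, c("code", "category", "label")])
  known <- c("lung_cancer", "scc", "symptom", "procedure", "surgery",
             "terminal_care", "comorbidity", "lifestyle", "encounter")
  bad <- setdiff(codes$category, known)
  if (length(bad)) {
    stop_config("unknown code category: ", paste(bad, collapse = ", "))
  }
  dup <- codes$code[duplicated(codes$code)]
  if (length(dup)) {
    stop_config("code(s) assigned to more than one category: ",
                paste(unique(dup), collapse = ", "))
  }
  if (!nrow(codes)) stop_config("empty code list")
  structure(codes, class = c("code_list", "data.frame"))
}

#' Load a code list from a CSV file
#'
#' Expects columns `code`, `category` and optionally `label`; validated and
#' deduplicated via [code_list()].
#'
#' @param path CSV file path.
#' @return A `code_list`.
#' @export
load_codelist <- function(path) {
  if (!file.exists(path)) stop_config("code list file not found: ", path)
  codes <- utils::read.csv(path, stringsAsFactors = FALSE)
  code_list(codes)
}

codes_of <- function(codelist, category) {
  codelist$code[codelist$category %in% category]
}

#' Built-in synthetic code list
#'
#' The code vocabulary the synthetic generator emits. These are synthetic
#' stand-in codes, not a real clinical dictionary.
#' @return A `code_list`.
#' @export
default_codes <- function() {
  load_codelist(system.file("extdata", "synthetic_codes.csv",
                            package = "sclcehr", mustWork = TRUE))
}

#' Text pattern sets for free-text case finding
#'
#' Holds the lower-cased search strings for the negation-aware free-text
#' scan: strings suggestive of SCLC, negation prefixes (a prefix such as
#' `"non"` immediately before an SCLC string marks the mention as NSCLC),
#' dedicated negated tokens (e.g. `"nsclc"`) and strings suggestive of
#' lung cancer.
#'
#' @param sclc_patterns,negation_prefixes,lung_patterns,negated_tokens
#'   Character vectors; the first three must be non-empty.
#' @return A `pattern_set` list.
#' @seealso [match_text()]
#' @export
pattern_set <- function(sclc_patterns, negation_prefixes, lung_patterns,
                        negated_tokens = character()) {
  lower <- function(x) unique(tolower(trimws(x)))
  ps <- list(sclc_patterns = lower(sclc_patterns),
             negation_prefixes = lower(negation_prefixes),
             lung_patterns = lower(lung_patterns),
             negated_tokens = lower(negated_tokens))
  for (nm in c("sclc_patterns", "negation_prefixes", "lung_patterns")) {
    if (!length(ps[[nm]]) || any(!nzchar(ps[[nm]]))) {
      stop_config("pattern set field '", nm, "' must be non-empty")
    }
  }
  structure(ps, class = "pattern_set")
}

#' Load a pattern set from a CSV file
#'
#' Expects columns `pattern` and `category` with categories `sclc`,
#' `negation`, `lung`, `negated_token`.
#'
#' @param path CSV file path.
#' @return A `pattern_set`.
#' @export
load_patterns <- function(path) {
  if (!file.exists(path)) stop_config("pattern file not found: ", path)
  pat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pattern", "category") %in% names(pat))) {
    stop_format("pattern file needs columns 'pattern' and 'category'")
  }
  bad <- setdiff(pat$category, c("sclc", "negation", "lung", "negated_token"))
  if (length(bad)) {
    stop_config("unknown pattern category: ", paste(bad, collapse = ", "))
  }
  pick <- function(cat) pat$pattern[pat$category == cat]
  pattern_set(pick("sclc"), pick("negation"), pick("lung"),
              pick("negated_token"))
}

#' Built-in pattern set
#'
#' Default SCLC / negation / lung-cancer search strings, including common
#' spelling and formatting variants.
#' @return A `pattern_set`.
#' @export
default_patterns <- function() {
  load_patterns(system.file("extdata", "default_patterns.csv",
                            package = "sclcehr", mustWork = TRUE))
}
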