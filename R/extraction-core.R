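# Rule-based feature extraction: regex models derived directly from the TNM
# value domains, the ICD-10 localization range filter, and the three-class
# return contract.

# token boundaries: a staging token must not sit inside a larger alphanumeric
# word, so e.g. the T of "Tumor" never matches
.B_L <- "(?<![A-Za-z0-9])"
.B_R <- "(?![A-Za-z0-9])"
.PREFIX <- "(?:yp|[cpry])?" # clinical/pathological/post-neoadjuvant prefixes

#' Regex specifications for the rule-based features
#'
#' One spec per rule-extracted feature. Each pattern is generated from the
#' feature's value domain ([tnm_domains()]), accepts the standard TNM
#' prefixes (c, p, r, y, yp) before T/N/M, requires token boundaries and is
#' matched case-insensitively. `x_is_empty` marks the features for which a
#' matched X is returned as class "empty" rather than as a value.
#'
#' @return named list of specs with fields `name`, `value_domain`, `pattern`,
#'   `x_is_empty`.
#' @export
feature_specs <- function() {
  dom <- tnm_domains()
  alt <- function(values) {
    # longest alternatives first so e.g. "4a" is not truncated to "4"
    v <- values[order(-nchar(values), values)]
    paste(v, collapse = "|")
  }
  spec <- function(name, prefix, x_is_empty) {
    list(
      name = name,
      value_domain = dom[[name]],
      pattern = paste0("(?i)", .B_L, if (prefix) .PREFIX else "",
                       name, "(", alt(dom[[name]]), ")", .B_R),
      x_is_empty = x_is_empty
    )
  }
  list(
    T = spec("T", prefix = TRUE,  x_is_empty = FALSE),
    N = spec("N", prefix = TRUE,  x_is_empty = FALSE),
    M = spec("M", prefix = TRUE,  x_is_empty = TRUE),
    L = spec("L", prefix = FALSE, x_is_empty = TRUE),
    V = spec("V", prefix = FALSE, x_is_empty = TRUE),
    R = spec("R", prefix = FALSE, x_is_empty = TRUE)
  )
}

# the lymph-node fraction "(affected/removed)" after the N value, with a
# standalone "a/b Lymphknoten" / "a/b lymph nodes" fallback
.FRACTION_PATTERN <- "\\((\\d{1,4})\\s*/\\s*(\\d{1,4})\\)"
.FRACTION_FALLBACK <- "(?<![\\d/])(\\d{1,4})\\s*/\\s*(\\d{1,4})(?=\\s+(?i:Lymphknoten|lymph))"

.ICD_PATTERN <- paste0(.B_L, "C\\d{2}(?:\\.\\d)?(?![A-Za-z0-9])")
.ICD_RANGE <- c(17.0, 22.1)

# run a perl regex over text; return matches with capture groups and spans
match_pattern <- function(text, pattern) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(match = character(), g1 = character(), g2 = character(),
                      start = integer(), end = integer()))
  }
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(match = character(), g1 = character(), g2 = character(),
                      start = integer(), end = integer()))
  }
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  grab <- function(k) {
    if (is.null(cs) || ncol(cs) < k) return(rep(NA_character_, length(starts)))
    out <- substring(text, cs[, k], cs[, k] + cl[, k] - 1L)
    out[cl[, k] == 0L & cs[, k] == 0L] <- NA_character_
    out
  }
  data.frame(match = substring(text, starts, ends), g1 = grab(1), g2 = grab(2),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

# canonical form of a matched staging value: the value domains use
# lower-case subdivision letters ("4a", "is") but an upper-case X
canon_value <- function(v) {
  v <- tolower(v)
  v[v == "x"] <- "X"
  v
}

# three-class decision from a set of matched values + spans
classify_matches <- function(feature, values, spans, x_is_empty = FALSE) {
  if (length(values) == 0L) {
    return(extraction_result(feature, NA, "empty"))
  }
  distinct <- unique(values)
  if (length(distinct) >= 2L) {
    return(extraction_result(feature, NA, "ambiguous", spans = spans))
  }
  if (x_is_empty && distinct == "X") {
    # "no statement possible": class 3, but the X hit is kept as provenance
    res <- extraction_result(feature, NA, "empty")
    res$spans <- spans
    return(res)
  }
  extraction_result(feature, distinct, "concrete", spans = spans)
}

#' Extract the TNM staging parameters from a finding text
#'
#' Applies the compiled regex model of every rule-based feature (T, N, M, L,
#' V, R and the lymph-node counts X1/X2) to a free-text pathology finding
#' and applies the three-class contract: exactly one distinct value is
#' returned as class "concrete", two or more distinct values as "ambiguous"
#' (expert validation required), zero hits as "empty". For M, L, V and R a
#' matched X also yields class "empty" (the finding states that no
#' assessment was possible) with the X span kept as provenance. Repeated
#' identical mentions are not a conflict and stay concrete.
#'
#' The lymph-node fraction is read from a parenthetical "(affected/removed)"
#' — by convention printed directly after the N value — so X2 is the first
#' and X1 the second number; a standalone "a/b Lymphknoten" phrasing is
#' accepted as fallback.
#'
#' @param text finding text (UTF-8 character scalar; `""` yields all-empty
#'   results).
#' @return named list of [extraction_result] objects for
#'   `T, N, M, L, V, R, X1, X2`.
#' @examples
#' r <- extract_tnm("Adenokarzinom. ypT3 ypN1a (2/25) L1 V0 R0 M0.")
#' r$T$value   # "3"
#' r$X1$value  # "25"
#' @export
extract_tnm <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  specs <- feature_specs()
  out <- list()
  for (f in names(specs)) {
    hits <- match_pattern(text, specs[[f]]$pattern)
    spans <- unname(Map(function(s, e) c(s, e), hits$start, hits$end))
    out[[f]] <- classify_matches(f, canon_value(hits$g1), spans,
                                 x_is_empty = specs[[f]]$x_is_empty)
  }
  frac <- rbind(match_pattern(text, .FRACTION_PATTERN),
                match_pattern(text, .FRACTION_FALLBACK))
  spans <- unname(Map(function(s, e) c(s, e), frac$start, frac$end))
  # fraction reads (X2 affected / X1 removed)
  out$X1 <- classify_matches("X1", frac$g2, spans)
  out$X2 <- classify_matches("X2", frac$g1, spans)
  out
}

# numeric position of an ICD-10 C code within chapter II, e.g. "C18.7" -> 18.7
icd_numeric <- function(code) {
  major <- as.numeric(substr(code, 2, 3))
  minor <- ifelse(nchar(code) >= 5, as.numeric(substr(code, 5, 5)) / 10, 0)
  major + minor
}

.icd_cache <- new.env(parent = emptyenv())

#' ICD-10 localization lookup table (digestive tract, C17.0-C22.1)
#'
#' Code-to-term table bundled with the package, covering the digestive-organ
#' range relevant for colorectal carcinoma localization. Term mapping is
#' best effort: a code inside the range but missing from this table is
#' still returned by [extract_icd_localization()], flagged `term_unmapped`.
#'
#' @return data.frame with columns `code`, `term`.
#' @export
icd_lookup <- function() {
  if (is.null(.icd_cache$table)) {
    path <- system.file("extdata", "icd10_digestive.csv", package = "oncodss")
    .icd_cache$table <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .icd_cache$table
}

#' Extract the tumor localization as an ICD-10 code
#'
#' Matches ICD-10 codes in the text, discards codes outside the digestive
#' tract range C17.0-C22.1 before the class decision (a finding may cite
#' out-of-scope codes, e.g. metastasis sites), then applies the three-class
#' contract to the surviving distinct codes. A concrete code is mapped to
#' its localization term via [icd_lookup()].
#'
#' @param text finding text.
#' @param lookup code/term table; defaults to the bundled [icd_lookup()].
#' @return an [extraction_result] for feature `"ICD"` with fields `term` and
#'   `term_unmapped`.
#' @examples
#' extract_icd_localization("Lokalisation: C18.7.")$value  # "C18.7"
#' extract_icd_localization("Metastase C34.1.")$result_class  # "empty"
#' @export
extract_icd_localization <- function(text, lookup = icd_lookup()) {
  stopifnot(is.character(text), length(text) == 1L)
  hits <- match_pattern(text, .ICD_PATTERN)
  if (nrow(hits) > 0L) {
    codes <- toupper(hits$match)
    keep <- icd_numeric(codes) >= .ICD_RANGE[1] & icd_numeric(codes) <= .ICD_RANGE[2]
    hits <- hits[keep, , drop = FALSE]
    codes <- codes[keep]
  } else {
    codes <- character()
  }
  spans <- unname(Map(function(s, e) c(s, e), hits$start, hits$end))
  res <- classify_matches("ICD", codes, spans)
  if (res$result_class == "concrete") {
    idx <- match(res$value, lookup$code)
    if (is.na(idx)) {
      res$term_unmapped <- TRUE
    } else {
      res$term <- lookup$term[idx]
    }
  }
  res
}

#' Traffic-light certainty band for a predicted-class probability
#'
#' Confidence display for ML-extracted features: green for p >= 0.95,
#' yellow for 0.90 <= p < 0.95, red for p < 0.90. Both boundaries are
#' inclusive on the more-confident side.
#'
#' @param p probability in \[0, 1\].
#' @return `"green"`, `"yellow"` or `"red"`.
#' @examples
#' certainty_band(0.95) # "green"
#' certainty_band(0.90) # "yellow"
#' certainty_band(0.80) # "red"
#' @export
certainty_band <- function(p) {
  check_prob(p, "p")
  if (p >= 0.95) "green" else if (p >= 0.90) "yellow" else "red"
}
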