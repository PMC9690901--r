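#' Construct an extraction result
#'
#' The return contract of every extractor: a feature either gets exactly one
#' distinct value (class `"concrete"`), conflicting distinct values
#' (`"ambiguous"`, value withheld so an expert can resolve it), or no usable
#' value (`"empty"`: zero pattern hits, or a matched X for M/L/V/R meaning
#' "no statement possible"). Provenance spans record which characters of the
#' source text produced each contributing match.
#'
#' @param feature feature identifier (one of T, N, M, L, V, R, X1, X2, ICD, NEO).
#' @param value extracted value as a character scalar, or `NA` for the
#'   ambiguous/empty classes.
#' @param result_class one of `"concrete"`, `"ambiguous"`, `"empty"`.
#' @param spans list of integer pairs `c(start, end)` — 1-based inclusive
#'   character offsets of contributing matches.
#' @param certainty predicted-class probability in \[0, 1\] (ML features only).
#' @param band certainty band from [certainty_band()], or `NA`.
#' @param term mapped localization term (ICD only), or `NA`.
#' @param term_unmapped logical marker: code in range but absent from lookup.
#' @return object of class `extraction_result`.
#' @export
extraction_result <- function(feature, value, result_class, spans = list(),
                              certainty = NA_real_, band = NA_character_,
                              term = NA_character_, term_unmapped = FALSE) {
  stopifnot(result_class %in% c("concrete", "ambiguous", "empty"))
  if (result_class == "concrete" && (length(value) != 1L || is.na(value))) {
    stop("concrete result requires exactly one value", call. = FALSE)
  }
  if (result_class != "concrete") value <- NA_character_
  if (result_class %in% c("concrete", "ambiguous") && length(spans) == 0L) {
    stop("non-empty result classes require provenance spans", call. = FALSE)
  }
  structure(
    list(feature = feature, value = value, result_class = result_class,
         spans = spans, certainty = certainty, band = band,
         term = term, term_unmapped = term_unmapped),
    class = "extraction_result"
  )
}

#' @export
print.extraction_result <- function(x, ...) {
  v <- if (is.na(x$value)) "-" else x$value
  cat(sprintf("[%s] %s (%s, %d span%s%s)\n", x$feature, v, x$result_class,
              length(x$spans), if (length(x$spans) == 1L) "" else "s",
              if (!is.na(x$certainty)) sprintf(", p=%.3f %s", x$certainty, x$band) else ""))
  invisible(x)
}
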