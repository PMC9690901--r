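# JSONL serialization of extraction bundles (the per-document JSON
# extraction schema: feature, value, class, spans, certainty, band).

result_to_list <- function(r) {
  list(feature = r$feature, value = r$value, result_class = r$result_class,
       spans = lapply(r$spans, function(s) as.integer(s)),
       certainty = r$certainty, band = r$band,
       term = r$term, term_unmapped = r$term_unmapped)
}

result_from_list <- function(obj) {
  r <- extraction_result(
    obj$feature,
    obj$value %||% NA_character_,
    obj$result_class,
    spans = lapply(obj$spans %||% list(), function(s) as.integer(unlist(s)))
  )
  r$certainty <- obj$certainty %||% NA_real_
  r$band <- obj$band %||% NA_character_
  r$term <- obj$term %||% NA_character_
  r$term_unmapped <- isTRUE(obj$term_unmapped)
  r
}

#' Write extraction bundles as JSONL
#'
#' One JSON object per line: `doc_id`, `status`, `flags`, `corrected` and
#' the per-feature results (value, class, spans, certainty, band).
#'
#' @param bundles list of `extraction_bundle`s.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_bundles_jsonl <- function(bundles, path) {
  lines <- vapply(bundles, function(b) {
    as.character(jsonlite::toJSON(
      list(doc_id = b$doc_id, status = b$status,
           flags = as.list(b$flags), corrected = as.list(b$corrected),
           results = lapply(b$results, result_to_list)),
      auto_unbox = TRUE, null = "null", na = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read extraction bundles from JSONL
#'
#' @param path file written by [write_bundles_jsonl()].
#' @return list of `extraction_bundle`s (without the source text).
#' @export
read_bundles_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    structure(
      list(doc_id = obj$doc_id, text = NA_character_,
           results = lapply(obj$results, result_from_list),
           flags = as.character(unlist(obj$flags)),
           status = obj$status,
           corrected = as.character(unlist(obj$corrected))),
      class = "extraction_bundle"
    )
  })
}
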