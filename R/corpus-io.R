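# Corpus serialization: JSONL (one document object per line), plain-text
# directory, and CSV ground-truth table.

truth_to_list <- function(truth) {
  list(T = truth$T, N = truth$N, M = truth$M, L = truth$L, V = truth$V,
       R = truth$R, X1 = truth$X1, X2 = truth$X2,
       neoadjuvant = truth$neoadjuvant,
       localization_code = truth$localization_code)
}

#' Write a corpus as JSONL
#'
#' One JSON object per line with fields `doc_id`, `text`, `truth`,
#' `perturbations`.
#'
#' @param corpus list of `finding_document`s.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    as.character(jsonlite::toJSON(
      list(doc_id = doc$doc_id, text = doc$text,
           truth = truth_to_list(doc$truth),
           perturbations = doc$perturbations),
      auto_unbox = TRUE, null = "null", na = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSONL corpus
#'
#' @param path file written by [write_corpus_jsonl()].
#' @return list of `finding_document`s.
#' @export
read_corpus_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    tr <- obj$truth
    truth <- tnm_record(T = tr$T, N = tr$N, M = tr$M, L = tr$L, V = tr$V,
                        R = tr$R, X1 = tr$X1, X2 = tr$X2,
                        neoadjuvant = tr$neoadjuvant,
                        localization_code = tr$localization_code %||% NA_character_)
    new_finding_document(obj$doc_id, obj$text, truth,
                         perturbations = obj$perturbations %||% list())
  })
}

#' Write a corpus as one text file per finding
#'
#' @param corpus list of `finding_document`s.
#' @param dir output directory (created if absent).
#' @return invisibly the written paths.
#' @export
write_corpus_txt <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(corpus, function(doc) {
    p <- file.path(dir, paste0(doc$doc_id, ".txt"))
    writeLines(doc$text, p, useBytes = TRUE)
    p
  }, "")
  invisible(paths)
}

#' Write the ground-truth table of a corpus as CSV
#'
#' One row per document: `doc_id` plus the ten feature columns.
#'
#' @param corpus list of `finding_document`s.
#' @param path output file.
#' @return invisibly the data.frame written.
#' @export
write_truth_csv <- function(corpus, path) {
  df <- do.call(rbind, lapply(corpus, function(doc) {
    tr <- doc$truth
    data.frame(doc_id = doc$doc_id, T = tr$T, N = tr$N, M = tr$M, L = tr$L,
               V = tr$V, R = tr$R, X1 = tr$X1, X2 = tr$X2,
               NEO = tr$neoadjuvant, ICD = tr$localization_code,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
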