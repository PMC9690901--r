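# Accuracy scoring of extraction output against ground truth: per-feature
# accuracies, complete-data accuracy, and disjoint document-level
# true/false/ambiguous counts.

#' Score extraction bundles against ground-truth records
#'
#' Per feature, an extraction counts as correct iff it is class concrete and
#' its value equals the truth — with one deliberate exception: for M, L, V
#' and R a truth of X is correctly reported as class empty with the X hit
#' recorded (the finding itself states that no assessment was possible), so
#' that case scores as correct. Ambiguous results and empties where the
#' truth holds a value are incorrect (the automated accuracy is penalized
#' for everything it hands to the expert).
#'
#' At the document level the three outcomes are disjoint: a document is
#' "true" iff every feature is correct, "ambiguous" iff any feature is
#' ambiguous (ambiguity takes precedence over plain errors — those documents
#' are routed to expert validation, not silently wrong), otherwise "false".
#' Complete-data accuracy is true/total.
#'
#' @param bundles list of `extraction_bundle`s (or named lists of
#'   [extraction_result]s) keyed like the truths.
#' @param truths list of [tnm_record()]s, same order and `doc_id`s.
#' @param features features to score (default: all ten, NEO included only
#'   when present in the bundles).
#' @return object of class `eval_report`: `per_feature_accuracy`,
#'   `complete_accuracy`, `counts` (true/false/ambiguous/total),
#'   `document_outcome`.
#' @export
score_corpus <- function(bundles, truths, features = NULL) {
  stopifnot(length(bundles) == length(truths))
  bundle_ids <- vapply(bundles, function(b) b$doc_id %||% NA_character_, "")
  truth_ids <- vapply(truths, function(tr) attr(tr, "doc_id") %||% NA_character_, "")
  if (!all(is.na(truth_ids)) && !all(is.na(bundle_ids))) {
    missing <- setdiff(truth_ids, bundle_ids)
    if (length(missing)) {
      stop("no predictions for doc ids: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    bundles <- bundles[match(truth_ids, bundle_ids)]
  }
  if (is.null(features)) {
    has_neo <- all(vapply(bundles, function(b) !is.null(b$results$NEO), TRUE))
    features <- if (has_neo) ALL_FEATURES else setdiff(ALL_FEATURES, "NEO")
  }
  n <- length(bundles)
  correct <- matrix(FALSE, n, length(features), dimnames = list(NULL, features))
  ambiguous <- matrix(FALSE, n, length(features), dimnames = list(NULL, features))
  for (i in seq_len(n)) {
    res <- bundles[[i]]$results %||% bundles[[i]]
    tr <- truths[[i]]
    for (f in features) {
      r <- res[[f]]
      if (is.null(r)) next
      ambiguous[i, f] <- r$result_class == "ambiguous"
      correct[i, f] <- feature_correct(r, tr, f)
    }
  }
  doc_true <- apply(correct, 1, all)
  doc_ambiguous <- !doc_true & apply(ambiguous, 1, any)
  doc_false <- !doc_true & !doc_ambiguous
  counts <- c(true = sum(doc_true), false = sum(doc_false),
              ambiguous = sum(doc_ambiguous), total = n)
  structure(
    list(per_feature_accuracy = colMeans(correct),
         complete_accuracy = sum(doc_true) / n,
         counts = counts,
         document_outcome = ifelse(doc_true, "true",
                                   ifelse(doc_ambiguous, "ambiguous", "false"))),
    class = "eval_report"
  )
}

# is one extraction result correct for one truth record?
feature_correct <- function(r, truth, feature) {
  tv <- truth_value(truth, feature)
  if (feature %in% X_EMPTY_FEATURES && !is.na(tv) && tv == "X") {
    # truth says "no statement possible": correct answer is an X-derived
    # empty (class 3 with the X hit recorded)
    return(r$result_class == "empty" && length(r$spans) > 0L)
  }
  if (is.na(tv)) return(r$result_class == "empty")
  r$result_class == "concrete" && !is.na(r$value) && r$value == tv
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_eval_report(x), sep = "\n")
  invisible(x)
}

#' Format an evaluation report as a text table
#'
#' Two blocks: per-feature extraction accuracy, and the disjoint
#' document-level correctness counts.
#'
#' @param x an `eval_report`.
#' @return character vector of lines.
#' @export
format_eval_report <- function(x) {
  acc <- x$per_feature_accuracy
  lines <- c("Accuracy of feature extraction",
             sprintf("  %-14s %7s", "Feature", "Acc."))
  lines <- c(lines, sprintf("  %-14s %6.2f%%", names(acc), 100 * acc))
  lines <- c(lines,
             sprintf("  %-14s %6.2f%%", "Complete data", 100 * x$complete_accuracy),
             "",
             "Overall correctness (document level)",
             sprintf("  True %d (%.2f%%)  False %d  Ambiguous %d  Total %d",
                     x$counts["true"], 100 * x$counts["true"] / x$counts["total"],
                     x$counts["false"], x$counts["ambiguous"], x$counts["total"]))
  lines
}

#' Serialize an evaluation report as JSON
#'
#' @param x an `eval_report`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
eval_report_json <- function(x, path = NULL) {
  obj <- list(per_feature_accuracy = as.list(x$per_feature_accuracy),
              complete_accuracy = x$complete_accuracy,
              counts = as.list(x$counts))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
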