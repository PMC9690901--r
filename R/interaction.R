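# Headless expert-interaction workflow: run all extractors over a finding,
# flag everything that needs human validation, apply corrections, export.
# Provenance is kept as character offsets into the ingested text.

#' Run the full extraction pipeline over one finding
#'
#' Applies [extract_tnm()], [extract_icd_localization()] and
#' [classify_neoadjuvant()] and assembles an extraction bundle. A feature is
#' flagged for expert validation when its result is ambiguous, empty with
#' zero hits (an X-derived empty for M/L/V/R carries its provenance span and
#' is accepted), or — for the ML feature — when the certainty band falls
#' below the flagging threshold (red by default; set
#' `flag_yellow = TRUE` to also queue yellow-band results).
#'
#' @param text finding text.
#' @param neo_model trained `neoadjuvant_model`, or `NULL` to skip the ML
#'   feature.
#' @param doc_id identifier carried into the bundle.
#' @param flag_yellow also flag yellow-band ML results (default `FALSE`).
#' @return object of class `extraction_bundle` with fields `doc_id`, `text`,
#'   `results`, `flags`, `status` (`"pending"`).
#' @export
process_document <- function(text, neo_model = NULL, doc_id = "doc-1",
                             flag_yellow = FALSE) {
  results <- extract_tnm(text)
  results$ICD <- extract_icd_localization(text)
  if (!is.null(neo_model)) {
    results$NEO <- classify_neoadjuvant(neo_model, text)
  }
  flags <- character()
  for (f in names(results)) {
    r <- results[[f]]
    needs <- r$result_class == "ambiguous" ||
      (r$result_class == "empty" && length(r$spans) == 0L) ||
      (!is.na(r$band) && (r$band == "red" || (flag_yellow && r$band == "yellow")))
    if (needs) flags <- c(flags, f)
  }
  structure(
    list(doc_id = doc_id, text = text, results = results, flags = flags,
         status = "pending", corrected = character()),
    class = "extraction_bundle"
  )
}

#' @export
print.extraction_bundle <- function(x, ...) {
  cat(sprintf("<extraction bundle %s: status %s, %d flag(s)%s>\n",
              x$doc_id, x$status, length(x$flags),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Apply expert corrections to a pending bundle
#'
#' Corrected values replace the extracted ones (result class becomes
#' concrete, the expert is the source of truth), flags for corrected
#' features are cleared, and one feedback event per correction is emitted
#' for [incorporate_feedback()]. Experts may override any value, flagged or
#' not. Values are validated against the feature domains before anything is
#' applied. The bundle moves from `"pending"` to `"validated"`; skipping or
#' repeating states is an error.
#'
#' @param bundle a pending `extraction_bundle`.
#' @param corrections named list or character vector, feature -> corrected
#'   value. May be empty (validation without changes).
#' @return list with the validated `bundle` and the list of feedback
#'   `events`.
#' @export
apply_validation <- function(bundle, corrections = list()) {
  stopifnot(inherits(bundle, "extraction_bundle"))
  if (bundle$status != "pending") {
    stop(sprintf("cannot validate a bundle in status '%s' (pending required)",
                 bundle$status), call. = FALSE)
  }
  corrections <- as.list(corrections)
  dom <- tnm_domains()
  # validate everything first so a bad correction leaves the bundle untouched
  for (f in names(corrections)) {
    value <- as.character(corrections[[f]])
    if (f %in% names(dom) && !value %in% dom[[f]]) {
      stop(sprintf("correction '%s' for %s outside domain {%s}",
                   value, f, paste(dom[[f]], collapse = ",")), call. = FALSE)
    }
    if (f %in% c("X1", "X2") && is.na(suppressWarnings(as.integer(value)))) {
      stop(sprintf("correction '%s' for %s outside domain {non-negative integers}",
                   value, f), call. = FALSE)
    }
    if (f == "NEO" && !value %in% c("TRUE", "FALSE")) {
      stop(sprintf("correction '%s' for NEO outside domain {TRUE,FALSE}", value),
           call. = FALSE)
    }
    if (!f %in% ALL_FEATURES) stop("unknown feature: ", f, call. = FALSE)
  }
  events <- list()
  for (f in names(corrections)) {
    value <- as.character(corrections[[f]])
    old <- bundle$results[[f]]
    events[[length(events) + 1L]] <- list(
      doc_id = bundle$doc_id, feature = f, corrected = value,
      extracted = if (is.null(old)) NA_character_ else old$value,
      text = bundle$text
    )
    bundle$results[[f]] <- extraction_result(f, value, "concrete",
                                             spans = list(c(1L, max(1L, nchar(bundle$text)))))
    bundle$corrected <- union(bundle$corrected, f)
    bundle$flags <- setdiff(bundle$flags, f)
  }
  bundle$status <- "validated"
  list(bundle = bundle, events = events)
}

#' Export a validated bundle for external systems
#'
#' Flattens the ten extracted features into one record with per-feature
#' provenance (result class, certainty band, corrected-by-expert flag) in a
#' deterministic field order, and moves the bundle to `"exported"`. JSON
#' yields one object; CSV yields a header plus one row (values only,
#' provenance columns suffixed `_class`, `_band`, `_corrected`).
#'
#' @param bundle a validated `extraction_bundle`.
#' @param format `"json"` or `"csv"`.
#' @return list with `payload` (character scalar: serialized record) and the
#'   updated `bundle`.
#' @export
export_payload <- function(bundle, format = c("json", "csv")) {
  stopifnot(inherits(bundle, "extraction_bundle"))
  format <- match.arg(format)
  if (bundle$status != "validated") {
    stop(sprintf("cannot export a bundle in status '%s' (validated required)",
                 bundle$status), call. = FALSE)
  }
  record <- export_record(bundle)
  payload <- if (format == "json") {
    jsonlite::toJSON(record, auto_unbox = TRUE, na = "null")
  } else {
    flat <- unlist(record, recursive = TRUE)
    paste(paste(names(flat), collapse = ","),
          paste(vapply(flat, function(v) if (is.na(v)) "" else as.character(v), ""),
                collapse = ","),
          sep = "\n")
  }
  bundle$status <- "exported"
  list(payload = as.character(payload), bundle = bundle)
}

# flat named record for one bundle, deterministic feature order
export_record <- function(bundle) {
  rec <- list(doc_id = bundle$doc_id)
  for (f in ALL_FEATURES) {
    r <- bundle$results[[f]]
    if (is.null(r)) {
      rec[[f]] <- list(value = NA, class = NA, band = NA, corrected = FALSE)
    } else {
      rec[[f]] <- list(value = r$value, class = r$result_class,
                       band = r$band, corrected = f %in% bundle$corrected)
    }
  }
  rec
}

#' Export several validated bundles as one CSV table
#'
#' @param bundles list of validated `extraction_bundle`s.
#' @param path optional file path; when `NULL` the CSV text is returned.
#' @return character scalar of CSV text (invisibly when written to `path`).
#' @export
export_csv <- function(bundles, path = NULL) {
  rows <- lapply(bundles, function(b) {
    if (b$status != "validated") {
      stop(sprintf("bundle %s is '%s', not validated", b$doc_id, b$status),
           call. = FALSE)
    }
    flat <- unlist(export_record(b), recursive = TRUE)
    vapply(flat, function(v) if (is.na(v)) "" else as.character(v), "")
  })
  header <- names(rows[[1]])
  lines <- c(paste(header, collapse = ","),
             vapply(rows, paste, "", collapse = ","))
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
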