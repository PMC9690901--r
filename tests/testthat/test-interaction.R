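# Validation workflow: flagging rules, the pending -> validated -> exported
# state machine, corrections, and export round-trips.

test_that("a clean document produces zero flags and a pending bundle", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  bundle <- process_document(doc$text, doc_id = doc$doc_id)
  expect_identical(bundle$status, "pending")
  expect_length(bundle$flags, 0L)
})

test_that("ambiguity, zero-hit emptiness and red bands are all flagged", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  dup <- perturb_document(doc, "conflicting_duplicate", feature = "T", seed = 1)
  expect_true("T" %in% process_document(dup$text)$flags)
  omit <- perturb_document(doc, "omission", feature = "R", seed = 1)
  expect_true("R" %in% process_document(omit$text)$flags)
  # an X-derived empty carries provenance and is not flagged
  xv <- perturb_document(doc, "x_value", feature = "V", seed = 1)
  expect_false("V" %in% process_document(xv$text)$flags)
  # red-band ML results are flagged; confident ones are not
  model <- small_neo_model()
  confident <- process_document(doc$text, neo_model = model)
  low <- structure(model, class = class(model))
  low$weights[] <- 0  # certainty collapses to 0.5 -> red band
  uncertain <- process_document(doc$text, neo_model = low)
  expect_true("NEO" %in% uncertain$flags)
  expect_identical(uncertain$results$NEO$band, "red")
})

test_that("yellow-band flagging is configurable and off by default", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  model <- small_neo_model()
  # craft a model with certainty in the yellow band on this document
  yellow <- model
  yellow$weights[] <- 0
  yellow$weights[1] <- stats::qlogis(0.92)
  b1 <- process_document(doc$text, neo_model = yellow)
  expect_identical(b1$results$NEO$band, "yellow")
  expect_false("NEO" %in% b1$flags)
  b2 <- process_document(doc$text, neo_model = yellow, flag_yellow = TRUE)
  expect_true("NEO" %in% b2$flags)
})

test_that("corrections replace values, clear flags and emit feedback events", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  dup <- perturb_document(doc, "conflicting_duplicate", feature = "T", seed = 1)
  bundle <- process_document(dup$text, doc_id = "d1")
  out <- apply_validation(bundle, list(T = doc$truth$T))
  expect_identical(out$bundle$status, "validated")
  expect_identical(out$bundle$results$T$value, doc$truth$T)
  expect_false("T" %in% out$bundle$flags)
  expect_length(out$events, 1L)
  expect_identical(out$events[[1]]$feature, "T")
  expect_identical(out$events[[1]]$doc_id, "d1")
})

test_that("experts may override unflagged values; event still emitted", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  bundle <- process_document(doc$text)
  expect_length(bundle$flags, 0L)
  out <- apply_validation(bundle, list(R = "1"))
  expect_length(out$events, 1L)
  expect_identical(out$bundle$results$R$value, "1")
})

test_that("empty validation produces no events; out-of-domain corrections rejected", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  bundle <- process_document(doc$text)
  out <- apply_validation(bundle)
  expect_identical(out$bundle$status, "validated")
  expect_length(out$events, 0L)
  expect_error(apply_validation(process_document(doc$text), list(T = "9")),
               "domain")
  expect_error(apply_validation(process_document(doc$text), list(NEO = "maybe")),
               "TRUE,FALSE")
})

test_that("the state machine admits no skipped or repeated transitions", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  bundle <- process_document(doc$text)
  expect_error(export_payload(bundle, "json"), "validated required")
  validated <- apply_validation(bundle)$bundle
  expect_error(apply_validation(validated), "pending required")
  exported <- export_payload(validated, "json")$bundle
  expect_identical(exported$status, "exported")
  expect_error(export_payload(exported, "json"), "validated required")
  expect_error(apply_validation(exported), "pending required")
})

test_that("JSON export carries exactly the ten features and round-trips values", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  model <- small_neo_model()
  validated <- apply_validation(process_document(doc$text, neo_model = model))$bundle
  payload <- export_payload(validated, "json")$payload
  parsed <- jsonlite::fromJSON(payload)
  expect_setequal(setdiff(names(parsed), "doc_id"),
                  c("T", "N", "M", "L", "V", "R", "X1", "X2", "ICD", "NEO"))
  for (f in c("T", "N", "X1", "X2", "ICD", "NEO")) {
    expect_identical(parsed[[f]]$value, validated$results[[f]]$value, info = f)
  }
})

test_that("CSV export yields one header plus one row per bundle", {
  corpus <- clean_corpus(n = 4, seed = 7)
  bundles <- lapply(corpus_bundles(corpus), function(b) apply_validation(b)$bundle)
  csv <- export_csv(bundles)
  lines <- strsplit(csv, "\n")[[1]]
  expect_length(lines, 5L)
  parsed <- utils::read.csv(text = csv, stringsAsFactors = FALSE)
  expect_identical(nrow(parsed), 4L)
  expect_identical(parsed$T.value, vapply(corpus, function(d) d$truth$T, ""))
})

test_that("every ambiguous or red result in a perturbed corpus ends up flagged", {
  corpus <- generate_corpus(corpus_config(n_documents = 60, seed = 51,
                                          ambiguity_rate = 0.4,
                                          omission_rate = 0.3))
  model <- small_neo_model()
  for (doc in corpus) {
    bundle <- process_document(doc$text, neo_model = model, doc_id = doc$doc_id)
    for (f in names(bundle$results)) {
      r <- bundle$results[[f]]
      if (r$result_class == "ambiguous" ||
          (r$result_class == "empty" && length(r$spans) == 0L) ||
          identical(r$band, "red")) {
        expect_true(f %in% bundle$flags, info = paste(doc$doc_id, f))
      }
    }
  }
})

test_that("bundles round-trip through JSONL", {
  corpus <- clean_corpus(n = 3, seed = 7)
  bundles <- corpus_bundles(corpus, neo_model = small_neo_model())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_bundles_jsonl(bundles, path)
  back <- read_bundles_jsonl(path)
  expect_length(back, 3L)
  for (i in seq_along(bundles)) {
    expect_identical(back[[i]]$doc_id, bundles[[i]]$doc_id)
    expect_identical(back[[i]]$status, bundles[[i]]$status)
    for (f in names(bundles[[i]]$results)) {
      expect_identical(back[[i]]$results[[f]]$value,
                       bundles[[i]]$results[[f]]$value, info = f)
      expect_identical(back[[i]]$results[[f]]$result_class,
                       bundles[[i]]$results[[f]]$result_class, info = f)
    }
  }
})
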