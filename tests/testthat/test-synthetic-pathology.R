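# Corpus generator: clean-generation contract, seeded determinism, logged
# perturbations at the configured rates, and per-feature perturbation
# soundness against the extraction oracle.

test_that("a clean corpus is recovered exactly by the extraction oracle", {
  corpus <- clean_corpus(n = 3, seed = 7)
  for (doc in corpus) {
    expect_length(doc$perturbations, 0L)
    res <- extract_tnm(doc$text)
    icd <- extract_icd_localization(doc$text)
    tr <- doc$truth
    for (f in c("T", "N", "M", "L", "V", "R")) {
      tv <- tr[[f]]
      if (f %in% c("M", "L", "V", "R") && tv == "X") {
        expect_identical(res[[f]]$result_class, "empty", info = f)
        expect_gt(length(res[[f]]$spans), 0L)
      } else {
        expect_identical(res[[f]]$value, tv, info = f)
      }
    }
    expect_identical(res$X1$value, as.character(tr$X1))
    expect_identical(res$X2$value, as.character(tr$X2))
    expect_identical(icd$value, tr$localization_code)
  }
})

test_that("oracle closure holds across a large seeded clean corpus", {
  corpus <- clean_corpus(n = 500, seed = 23)
  bundles <- corpus_bundles(corpus)
  report <- score_corpus(bundles, corpus_truths(corpus))
  expect_identical(unname(report$counts["true"]), 500L)
  expect_true(all(report$per_feature_accuracy == 1))
})

test_that("identical configs produce byte-identical corpora", {
  c1 <- generate_corpus(corpus_config(n_documents = 50, seed = 5,
                                      ambiguity_rate = 0.2,
                                      ocr_noise_rate = 0.01))
  c2 <- generate_corpus(corpus_config(n_documents = 50, seed = 5,
                                      ambiguity_rate = 0.2,
                                      ocr_noise_rate = 0.01))
  expect_identical(c1, c2)
  expect_false(identical(
    c1, generate_corpus(corpus_config(n_documents = 50, seed = 6,
                                      ambiguity_rate = 0.2,
                                      ocr_noise_rate = 0.01))))
})

test_that("invalid configurations are rejected", {
  expect_error(corpus_config(n_documents = 0), "positive")
  expect_error(corpus_config(ambiguity_rate = 1.4), "probability")
  expect_error(corpus_config(language_template = "xx"), "template")
})

test_that("logged conflicting duplicates occur at the configured binomial rate", {
  corpus <- generate_corpus(corpus_config(n_documents = 200, seed = 1,
                                          ambiguity_rate = 0.1))
  n_dup <- sum(vapply(corpus, function(d) {
    any(vapply(d$perturbations, function(p) p$kind == "conflicting_duplicate",
               TRUE))
  }, TRUE))
  ci <- binom_99(200, 0.1)
  expect_gte(n_dup, ci[1])
  expect_lte(n_dup, ci[2])
})

test_that("every perturbation kind forces its contract class, per feature", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  class_of <- function(text, f) {
    if (f == "X12") return(extract_tnm(text)$X1$result_class)
    if (f == "ICD") return(extract_icd_localization(text)$result_class)
    extract_tnm(text)[[f]]$result_class
  }
  for (f in c("T", "N", "M", "L", "V", "R", "X12", "ICD")) {
    dup <- perturb_document(doc, "conflicting_duplicate", feature = f, seed = 9)
    expect_identical(class_of(dup$text, f), "ambiguous", info = f)
    expect_identical(dup$perturbations[[1]]$kind, "conflicting_duplicate")
    omit <- perturb_document(doc, "omission", feature = f, seed = 9)
    expect_identical(class_of(omit$text, f), "empty", info = f)
  }
  for (f in c("M", "L", "V", "R")) {
    xv <- perturb_document(doc, "x_value", feature = f, seed = 9)
    res <- extract_tnm(xv$text)[[f]]
    expect_identical(res$result_class, "empty", info = f)
    expect_gt(length(res$spans), 0L)
  }
  expect_error(perturb_document(doc, "x_value", feature = "T"), "M, L, V, R")
  expect_error(perturb_document(doc, "x_value", feature = "N"), "M, L, V, R")
})

test_that("OCR noise substitutes at the configured rate and respects protection", {
  doc <- clean_corpus(n = 3, seed = 7)[[1]]
  chars <- strsplit(doc$text, "")[[1]]
  protected <- logical(length(chars))
  for (span in oncodss:::truth_token_spans(doc$text)) {
    protected[span[1]:span[2]] <- TRUE
  }
  n_eligible <- sum(grepl("[A-Za-z0-9]", chars) & !protected)
  rate <- 0.05
  noisy <- perturb_document(doc, "ocr_noise", rate = rate, seed = 4)
  dist <- utils::adist(doc$text, noisy$text)[1, 1]
  ci <- binom_99(n_eligible, rate)
  expect_gte(dist, ci[1])
  expect_lte(dist, ci[2])
  # protection keeps the staging tokens intact
  res <- extract_tnm(noisy$text)
  tr <- doc$truth
  expect_identical(res$T$value, tr$T)
  expect_identical(res$X1$value, as.character(tr$X1))
})

test_that("narrative templates never collide with the extraction patterns", {
  expect_true(lint_template_set("de"))
  expect_true(lint_template_set("en"))
  expect_true(lint_template_set("de_alt"))
})

test_that("corpus round-trips through JSONL, and sidecar formats are written", {
  corpus <- clean_corpus(n = 5, seed = 7)
  dir <- withr::local_tempdir()
  jsonl <- file.path(dir, "corpus.jsonl")
  write_corpus_jsonl(corpus, jsonl)
  expect_length(readLines(jsonl), 5L)
  back <- read_corpus_jsonl(jsonl)
  expect_identical(lapply(back, `[[`, "text"), lapply(corpus, `[[`, "text"))
  expect_identical(lapply(back, function(d) unclass(d$truth)),
                   lapply(corpus, function(d) unclass(d$truth)))
  paths <- write_corpus_txt(corpus, file.path(dir, "txt"))
  expect_length(paths, 5L)
  truth <- write_truth_csv(corpus, file.path(dir, "truth.csv"))
  expect_identical(dim(truth), c(5L, 11L))
})
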