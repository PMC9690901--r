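# Scoring: per-feature accuracy, complete-data accuracy, and the disjoint
# true/false/ambiguous document counts.

# build a bundle with given per-feature results straight from truth
bundle_from_truth <- function(truth, doc_id = "d") {
  results <- list()
  for (f in c("T", "N", "M", "L", "V", "R")) {
    tv <- truth[[f]]
    results[[f]] <- if (f %in% c("M", "L", "V", "R") && tv == "X") {
      r <- extraction_result(f, NA, "empty")
      r$spans <- list(c(1L, 2L))
      r
    } else {
      extraction_result(f, tv, "concrete", spans = list(c(1L, 2L)))
    }
  }
  results$X1 <- extraction_result("X1", as.character(truth$X1), "concrete",
                                  spans = list(c(1L, 2L)))
  results$X2 <- extraction_result("X2", as.character(truth$X2), "concrete",
                                  spans = list(c(1L, 2L)))
  results$ICD <- extraction_result("ICD", truth$localization_code, "concrete",
                                   spans = list(c(1L, 2L)))
  structure(list(doc_id = doc_id, results = results, flags = character(),
                 status = "pending", corrected = character()),
            class = "extraction_bundle")
}

fixture_truth <- function() {
  tnm_record(T = "3", N = "1a", M = "0", L = "1", V = "0", R = "0",
             X1 = 20, X2 = 2, neoadjuvant = FALSE, localization_code = "C18.7")
}

test_that("a hand-built mixed corpus is counted exactly (8 true, 1 false, 1 ambiguous)", {
  truths <- replicate(10, fixture_truth(), simplify = FALSE)
  bundles <- lapply(1:10, function(i) bundle_from_truth(truths[[i]],
                                                        paste0("d", i)))
  # one wrong value
  bundles[[9]]$results$R <- extraction_result("R", "1", "concrete",
                                              spans = list(c(1L, 2L)))
  # one ambiguous
  bundles[[10]]$results$T <- extraction_result("T", NA, "ambiguous",
                                               spans = list(c(1L, 2L), c(3L, 4L)))
  report <- score_corpus(bundles, truths)
  expect_identical(unname(report$counts),
                   c(8L, 1L, 1L, 10L))
  expect_equal(report$complete_accuracy, 0.8)
  expect_equal(unname(report$per_feature_accuracy["R"]), 0.9)
  expect_equal(unname(report$per_feature_accuracy["T"]), 0.9)
  expect_equal(unname(report$per_feature_accuracy["N"]), 1)
})

test_that("identity predictions score perfectly", {
  truths <- replicate(6, fixture_truth(), simplify = FALSE)
  bundles <- lapply(1:6, function(i) bundle_from_truth(truths[[i]],
                                                       paste0("d", i)))
  report <- score_corpus(bundles, truths)
  expect_true(all(report$per_feature_accuracy == 1))
  expect_identical(unname(report$counts), c(6L, 0L, 0L, 6L))
  expect_equal(report$complete_accuracy, 1)
})

test_that("a single wrong feature is localized to that feature's accuracy", {
  truths <- replicate(5, fixture_truth(), simplify = FALSE)
  bundles <- lapply(1:5, function(i) bundle_from_truth(truths[[i]],
                                                       paste0("d", i)))
  bundles[[3]]$results$R <- extraction_result("R", "2", "concrete",
                                              spans = list(c(1L, 2L)))
  report <- score_corpus(bundles, truths)
  expect_equal(unname(report$per_feature_accuracy["R"]), 4 / 5)
  others <- report$per_feature_accuracy[setdiff(names(report$per_feature_accuracy), "R")]
  expect_true(all(others == 1))
})

test_that("ambiguity takes precedence over error at the document level", {
  truths <- replicate(2, fixture_truth(), simplify = FALSE)
  bundles <- lapply(1:2, function(i) bundle_from_truth(truths[[i]],
                                                       paste0("d", i)))
  # document 2 has both a wrong value and an ambiguity -> counted ambiguous
  bundles[[2]]$results$R <- extraction_result("R", "1", "concrete",
                                              spans = list(c(1L, 2L)))
  bundles[[2]]$results$T <- extraction_result("T", NA, "ambiguous",
                                              spans = list(c(1L, 2L), c(3L, 4L)))
  report <- score_corpus(bundles, truths)
  expect_identical(unname(report$counts), c(1L, 0L, 1L, 2L))
})

test_that("a truth of X for M/L/V/R counts correct only as an X-derived empty", {
  truth <- tnm_record(T = "3", N = "0", M = "X", L = "0", V = "0", R = "0",
                      X1 = 10, X2 = 0, neoadjuvant = FALSE,
                      localization_code = "C20")
  good <- bundle_from_truth(truth)
  report <- score_corpus(list(good), list(truth))
  expect_equal(unname(report$per_feature_accuracy["M"]), 1)
  # a zero-hit empty (no X span) does not count
  bad <- good
  bad$results$M <- extraction_result("M", NA, "empty")
  report2 <- score_corpus(list(bad), list(truth))
  expect_equal(unname(report2$per_feature_accuracy["M"]), 0)
})

test_that("report invariants hold on random perturbed corpora, order-invariantly", {
  corpus <- generate_corpus(corpus_config(n_documents = 80, seed = 77,
                                          ambiguity_rate = 0.25,
                                          omission_rate = 0.25))
  bundles <- corpus_bundles(corpus)
  truths <- corpus_truths(corpus)
  report <- score_corpus(bundles, truths)
  expect_identical(unname(report$counts["true"] + report$counts["false"] +
                            report$counts["ambiguous"]),
                   unname(report$counts["total"]))
  expect_true(all(report$per_feature_accuracy >= 0 &
                    report$per_feature_accuracy <= 1))
  expect_equal(report$complete_accuracy,
               unname(report$counts["true"] / report$counts["total"]))
  perm <- withr::with_seed(1, sample(seq_along(bundles)))
  report2 <- score_corpus(bundles[perm], truths[perm])
  expect_equal(report2$per_feature_accuracy, report$per_feature_accuracy)
  expect_identical(report2$counts, report$counts)
})

test_that("mismatched document ids are reported by id", {
  corpus <- clean_corpus(n = 3, seed = 7)
  bundles <- corpus_bundles(corpus)
  truths <- corpus_truths(corpus)
  attr(truths[[2]], "doc_id") <- "doc-x"
  expect_error(score_corpus(bundles, truths), "doc-x")
})

test_that("reports serialize to JSON and a readable table", {
  corpus <- clean_corpus(n = 5, seed = 7)
  report <- score_corpus(corpus_bundles(corpus), corpus_truths(corpus))
  json <- jsonlite::fromJSON(eval_report_json(report))
  expect_equal(json$complete_accuracy, 1)
  expect_identical(json$counts$total, 5L)
  lines <- format_eval_report(report)
  expect_true(any(grepl("Complete data", lines)))
  expect_true(any(grepl("True 5", lines)))
})
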