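# shared fixtures, built in code at test time

# small clean corpus, memoised per (n, seed) within one test run
.fixture_env <- new.env(parent = emptyenv())

clean_corpus <- function(n = 50, seed = 7, ...) {
  key <- paste0("corpus_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_corpus(
      corpus_config(n_documents = n, seed = seed, ...))
  }
  .fixture_env[[key]]
}

corpus_texts <- function(corpus) vapply(corpus, `[[`, "", "text")
corpus_labels <- function(corpus) {
  vapply(corpus, function(d) d$truth$neoadjuvant, TRUE)
}

# neoadjuvant model trained on a small seeded corpus
small_neo_model <- function(n = 120, seed = 100) {
  key <- paste0("neo_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    corpus <- generate_corpus(corpus_config(n_documents = n, seed = seed))
    .fixture_env[[key]] <- train_neoadjuvant(corpus_texts(corpus),
                                             corpus_labels(corpus),
                                             seed = seed)
  }
  .fixture_env[[key]]
}

# process a corpus into bundles (without the ML feature unless asked)
corpus_bundles <- function(corpus, neo_model = NULL) {
  lapply(corpus, function(doc) {
    process_document(doc$text, neo_model = neo_model, doc_id = doc$doc_id)
  })
}

corpus_truths <- function(corpus) {
  lapply(corpus, function(doc) {
    tr <- doc$truth
    attr(tr, "doc_id") <- doc$doc_id
    tr
  })
}

# small cohort, memoised
small_cohort <- function(n = 600, seed = 11, ...) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      cohort_config(n_patients = n, seed = seed, ...))
  }
  .fixture_env[[key]]
}

# central 99% interval of a Binomial(n, p) count
binom_99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p)
}
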