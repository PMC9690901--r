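# ML extraction of the neoadjuvant-therapy flag: bag-of-words token counts
# into L1-regularized (lasso) logistic regression, with certainty banding and
# feedback-driven retraining from expert corrections.

#' Tokenize a finding text for the bag-of-words model
#'
#' Lower-cases, splits on non-letter characters and drops tokens shorter
#' than two characters. Raw counts (no tf-idf weighting) feed the frequency
#' matrix.
#'
#' @param text character vector of documents.
#' @return list of character vectors (tokens per document).
#' @export
tokenize <- function(text) {
  lapply(strsplit(tolower(text), "[^a-zäöüß]+"), function(tok) {
    tok[nchar(tok) >= 2L]
  })
}

# token-frequency matrix over a fixed vocabulary (docs x vocabulary)
bow_matrix <- function(tokens, vocabulary) {
  m <- matrix(0L, nrow = length(tokens), ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(tokens)) {
    tab <- table(tokens[[i]])
    keep <- intersect(names(tab), vocabulary)
    m[i, keep] <- as.integer(tab[keep])
  }
  m
}

#' Train the neoadjuvant-therapy classifier
#'
#' Fits an L1-penalized (lasso) logistic regression on the token-frequency
#' (bag-of-words) matrix of labeled findings. The L1 penalty keeps the model
#' sparse so that the decisive tokens can be read off its weights. Training
#' is deterministic given corpus, tokenizer and seed.
#'
#' @param texts character vector of finding texts.
#' @param labels logical vector: was neoadjuvant therapy given?
#' @param l1_strength lasso penalty (glmnet lambda); larger values shrink
#'   all token weights toward zero, ending at the intercept-only model.
#' @param seed seed for the solver.
#' @return object of class `neoadjuvant_model` with fields `vocabulary`,
#'   `weights` (named, intercept first), `l1_strength`, `training_log`.
#' @export
train_neoadjuvant <- function(texts, labels, l1_strength = 0.01, seed = 1) {
  stopifnot(length(texts) == length(labels), is.logical(labels))
  if (!is.numeric(l1_strength) || l1_strength <= 0) {
    stop("`l1_strength` must be a positive real", call. = FALSE)
  }
  n_pos <- sum(labels)
  if (n_pos == 0L || n_pos == length(labels)) {
    missing <- if (n_pos == 0L) "positive (neoadjuvant)" else "negative (no neoadjuvant)"
    stop(sprintf("training corpus contains no %s documents; both classes are required",
                 missing), call. = FALSE)
  }
  tokens <- tokenize(texts)
  vocabulary <- sort(unique(unlist(tokens)))
  x <- bow_matrix(tokens, vocabulary)
  fit <- withr::with_seed(seed, {
    glmnet::glmnet(x, factor(labels, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 1,
                   lambda = l1_strength, standardize = FALSE)
  })
  beta <- as.numeric(fit$beta[, 1])
  weights <- c(intercept = as.numeric(fit$a0), stats::setNames(beta, vocabulary))
  structure(
    list(vocabulary = vocabulary, weights = weights, l1_strength = l1_strength,
         seed = seed,
         training_log = list(n_documents = length(texts), n_positive = n_pos)),
    class = "neoadjuvant_model"
  )
}

#' @export
print.neoadjuvant_model <- function(x, ...) {
  nz <- sum(x$weights[-1] != 0)
  cat(sprintf("neoadjuvant model: %d docs (%d positive), vocabulary %d, %d non-zero weights, lambda=%g\n",
              x$training_log$n_documents, x$training_log$n_positive,
              length(x$vocabulary), nz, x$l1_strength))
  invisible(x)
}

# positive-class probability for texts under a trained model
neoadjuvant_prob <- function(model, texts) {
  x <- bow_matrix(tokenize(texts), model$vocabulary)
  eta <- model$weights[1] + drop(x %*% model$weights[-1])
  stats::plogis(eta)
}

#' Classify the neoadjuvant-therapy status of a finding
#'
#' Applies a trained bag-of-words model; the result is always class
#' "concrete" with a boolean value, a certainty equal to the probability of
#' the predicted class, and the traffic-light band from [certainty_band()]
#' attached. Low-certainty (red) results are flagged for expert validation
#' downstream.
#'
#' @param model a trained `neoadjuvant_model`.
#' @param text finding text.
#' @return an [extraction_result] for feature `"NEO"`.
#' @export
classify_neoadjuvant <- function(model, text) {
  if (!inherits(model, "neoadjuvant_model")) {
    stop("`model` must be a trained neoadjuvant_model", call. = FALSE)
  }
  p_pos <- neoadjuvant_prob(model, text)
  label <- p_pos >= 0.5
  certainty <- max(p_pos, 1 - p_pos)
  res <- extraction_result("NEO", as.character(label), "concrete",
                           spans = list(c(1L, max(1L, nchar(text)))),
                           certainty = certainty,
                           band = certainty_band(certainty))
  res
}

#' Create an empty feedback store
#'
#' Persistent accumulator for expert corrections: validated labels (with
#' their source texts) for the ML feature, and per-pattern discrepancy
#' statistics for the rule-based features. Rules are never auto-modified;
#' their correction counts are surfaced for human rule revision.
#'
#' @return object of class `feedback_store`.
#' @export
feedback_store <- function() {
  structure(
    list(neo_texts = character(), neo_labels = logical(),
         neo_doc_ids = character(),
         rule_corrections = data.frame(doc_id = character(),
                                       feature = character(),
                                       extracted = character(),
                                       corrected = character(),
                                       stringsAsFactors = FALSE)),
    class = "feedback_store"
  )
}

#' Fold expert corrections into the extraction models
#'
#' Corrections from the validation workflow are appended to the feedback
#' store; the neoadjuvant model is then retrained from scratch on the
#' original corpus plus all stored corrections (retraining from the full
#' accumulated store keeps the model deterministic and reproducible).
#' Corrections to rule-based features only update the per-feature
#' discrepancy log. Out-of-domain corrected values are rejected with the
#' admissible domain listed.
#'
#' @param store a `feedback_store`.
#' @param corrections list of correction events, each a list with fields
#'   `doc_id`, `feature`, `corrected` (value), `text` (source text; required
#'   for feature `"NEO"`), optional `extracted`.
#' @param model current `neoadjuvant_model`, or `NULL`.
#' @param base_texts,base_labels the original training corpus the model is
#'   retrained on (together with the store).
#' @return list with the updated `store` and retrained `model` (the model is
#'   unchanged when no NEO corrections arrive).
#' @export
incorporate_feedback <- function(store, corrections, model = NULL,
                                 base_texts = character(),
                                 base_labels = logical()) {
  stopifnot(inherits(store, "feedback_store"))
  dom <- tnm_domains()
  neo_added <- FALSE
  for (corr in corrections) {
    f <- corr$feature
    value <- as.character(corr$corrected)
    if (f %in% names(dom)) {
      if (!value %in% dom[[f]]) {
        stop(sprintf("correction '%s' for %s outside domain {%s}",
                     value, f, paste(dom[[f]], collapse = ",")), call. = FALSE)
      }
      store$rule_corrections <- rbind(
        store$rule_corrections,
        data.frame(doc_id = corr$doc_id %||% NA_character_, feature = f,
                   extracted = as.character(corr$extracted %||% NA),
                   corrected = value, stringsAsFactors = FALSE))
    } else if (f %in% c("X1", "X2", "ICD")) {
      if (f %in% c("X1", "X2") && is.na(suppressWarnings(as.integer(value)))) {
        stop(sprintf("correction '%s' for %s outside domain {non-negative integers}",
                     value, f), call. = FALSE)
      }
      store$rule_corrections <- rbind(
        store$rule_corrections,
        data.frame(doc_id = corr$doc_id %||% NA_character_, feature = f,
                   extracted = as.character(corr$extracted %||% NA),
                   corrected = value, stringsAsFactors = FALSE))
    } else if (f == "NEO") {
      if (!value %in% c("TRUE", "FALSE")) {
        stop(sprintf("correction '%s' for NEO outside domain {TRUE,FALSE}", value),
             call. = FALSE)
      }
      if (is.null(corr$text)) {
        stop("NEO corrections must carry the source text", call. = FALSE)
      }
      store$neo_texts <- c(store$neo_texts, corr$text)
      store$neo_labels <- c(store$neo_labels, as.logical(value))
      store$neo_doc_ids <- c(store$neo_doc_ids, corr$doc_id %||% NA_character_)
      neo_added <- TRUE
    } else {
      stop("unknown feature in correction: ", f, call. = FALSE)
    }
  }
  if (neo_added) {
    model <- train_neoadjuvant(
      c(base_texts, store$neo_texts),
      c(base_labels, store$neo_labels),
      l1_strength = if (is.null(model)) 0.01 else model$l1_strength,
      seed = if (is.null(model)) 1 else model$seed
    )
  }
  list(store = store, model = model)
}
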