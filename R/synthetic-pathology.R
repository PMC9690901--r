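# Synthetic pathology-finding corpus: templated German/English findings with
# a known staging truth and controlled, fully logged imperfections, standing
# in for real (unpublishable) colorectal pathology reports.

#' Configuration for a synthetic finding corpus
#'
#' @param n_documents number of findings to generate (default 430, the size
#'   of a typical two-year colorectal extraction study at one center).
#' @param seed integer seed; identical configs yield byte-identical corpora.
#' @param ambiguity_rate per-document probability of injecting a conflicting
#'   duplicate mention of one randomly chosen feature.
#' @param omission_rate per-document probability of deleting all mentions of
#'   one randomly chosen feature.
#' @param ocr_noise_rate per-character substitution probability emulating
#'   OCR degradation (0 disables).
#' @param neoadjuvant_prevalence probability that a finding reports
#'   neoadjuvant pretreatment.
#' @param language_template template set identifier (see [template_set()]).
#' @param protect_truth_tokens if `TRUE` (default) OCR noise never corrupts
#'   the staging formula or ICD code; disable for stress testing.
#' @return object of class `corpus_config`.
#' @export
corpus_config <- function(n_documents = 430, seed = 1,
                          ambiguity_rate = 0, omission_rate = 0,
                          ocr_noise_rate = 0, neoadjuvant_prevalence = 0.3,
                          language_template = "de",
                          protect_truth_tokens = TRUE) {
  n_documents <- check_count(n_documents, "n_documents")
  check_prob(ambiguity_rate, "ambiguity_rate")
  check_prob(omission_rate, "omission_rate")
  check_prob(ocr_noise_rate, "ocr_noise_rate")
  check_prob(neoadjuvant_prevalence, "neoadjuvant_prevalence")
  template_set(language_template) # validates the id
  structure(
    list(n_documents = n_documents, seed = as.integer(seed),
         ambiguity_rate = ambiguity_rate, omission_rate = omission_rate,
         ocr_noise_rate = ocr_noise_rate,
         neoadjuvant_prevalence = neoadjuvant_prevalence,
         language_template = language_template,
         protect_truth_tokens = protect_truth_tokens),
    class = "corpus_config"
  )
}

# draw one staging truth from the value domains (weights reflect a typical
# resected colorectal cohort: mostly T2/T3, node-negative, M0, R0)
sample_truth <- function(neo_prev, icd_codes) {
  dom <- tnm_domains()
  Tv <- sample(dom$T, 1, prob = c(0.02, 0.02, 0.12, 0.25, 0.35, 0.12, 0.06, 0.04, 0.02))
  Nv <- sample(dom$N, 1, prob = c(0.40, 0.10, 0.15, 0.10, 0.03, 0.08, 0.07, 0.05, 0.02))
  Mv <- sample(dom$M, 1, prob = c(0.75, 0.08, 0.04, 0.03, 0.02, 0.08))
  Lv <- sample(dom$L, 1, prob = c(0.60, 0.35, 0.05))
  Vv <- sample(dom$V, 1, prob = c(0.65, 0.20, 0.10, 0.05))
  Rv <- sample(dom$R, 1, prob = c(0.80, 0.12, 0.04, 0.04))
  X1 <- sample(8:40, 1)
  X2 <- if (Nv %in% c("0", "X")) 0L else min(X1, 1L + stats::rbinom(1, X1 - 1L, 0.12))
  tnm_record(T = Tv, N = Nv, M = Mv, L = Lv, V = Vv, R = Rv,
             X1 = X1, X2 = X2,
             neoadjuvant = stats::runif(1) < neo_prev,
             localization_code = sample(icd_codes, 1))
}

# render the finding text for a truth record; RNG state supplies variant picks
render_finding <- function(truth, tpl) {
  prefix <- if (truth$neoadjuvant) "yp" else sample(c("p", "c"), 1, prob = c(0.8, 0.2))
  tnm_line <- paste0(
    tpl$tnm_label,
    prefix, "T", truth$T, " ",
    prefix, "N", truth$N, " (", truth$X2, "/", truth$X1, ") ",
    "M", truth$M, " L", truth$L, " V", truth$V, " R", truth$R, "."
  )
  loc_line <- paste0(tpl$loc_label, truth$localization_code, ".")
  neo_line <- if (truth$neoadjuvant) sample(tpl$neo_pos, 1) else sample(tpl$neo_neg, 1)
  paste(
    sample(tpl$clinical, 1),
    sample(tpl$macro, 1),
    sample(tpl$micro, 1),
    neo_line,
    loc_line,
    tnm_line,
    sample(tpl$assessment, 1),
    sep = "\n"
  )
}

new_finding_document <- function(doc_id, text, truth, perturbations = list()) {
  structure(list(doc_id = doc_id, text = text, truth = truth,
                 perturbations = perturbations),
            class = "finding_document")
}

#' @export
print.finding_document <- function(x, ...) {
  cat(sprintf("<finding %s: %d chars, %d perturbation(s)>\n",
              x$doc_id, nchar(x$text), length(x$perturbations)))
  invisible(x)
}

#' Generate a synthetic finding corpus
#'
#' Draws one staging truth per document from the TNM value domains, renders
#' it through the configured template set (narrative filler interleaved with
#' the formula and localization lines), and then injects defects
#' independently per document at the configured rates: a conflicting
#' duplicate mention (ambiguity), deletion of all mentions of a feature
#' (omission), and character-level OCR noise. Every injected defect is
#' recorded in the document's perturbation log, so generated corpora carry a
#' complete provenance of their imperfections.
#'
#' With all rates at zero, running the extractors on any generated document
#' recovers its truth exactly (the clean-generation contract).
#'
#' @param config a [corpus_config()].
#' @return list of `finding_document` objects.
#' @examples
#' corpus <- generate_corpus(corpus_config(n_documents = 3, seed = 7))
#' extract_tnm(corpus[[1]]$text)$T$value == corpus[[1]]$truth$T
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  tpl <- template_set(config$language_template)
  icd_codes <- icd_lookup()$code
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_documents), function(i) {
      truth <- sample_truth(config$neoadjuvant_prevalence, icd_codes)
      doc <- new_finding_document(sprintf("doc-%05d", i),
                                  render_finding(truth, tpl), truth)
      if (stats::runif(1) < config$ambiguity_rate) {
        feature <- sample(c("T", "N", "M", "L", "V", "R", "X12", "ICD"), 1)
        doc <- perturb_document(doc, "conflicting_duplicate", feature = feature)
      }
      if (stats::runif(1) < config$omission_rate) {
        feature <- sample(c("T", "N", "M", "L", "V", "R", "X12", "ICD"), 1)
        doc <- perturb_document(doc, "omission", feature = feature)
      }
      if (config$ocr_noise_rate > 0) {
        doc <- perturb_document(doc, "ocr_noise", rate = config$ocr_noise_rate,
                                protect = config$protect_truth_tokens)
      }
      doc
    })
  })
}

# character spans (start, end) of every truth-critical token in the text
truth_token_spans <- function(text) {
  patterns <- c(vapply(feature_specs(), `[[`, "", "pattern"),
                .FRACTION_PATTERN, .FRACTION_FALLBACK, .ICD_PATTERN)
  spans <- list()
  for (p in patterns) {
    hits <- match_pattern(text, p)
    if (nrow(hits) > 0L) {
      spans <- c(spans, Map(function(s, e) c(s, e), hits$start, hits$end))
    }
  }
  spans
}

# a rendered token for a feature/value pair, used for duplicate injection
render_token <- function(feature, value) {
  switch(feature,
    T = paste0("pT", value), N = paste0("pN", value),
    M = paste0("M", value), L = paste0("L", value),
    V = paste0("V", value), R = paste0("R", value),
    X12 = value, ICD = value,
    stop("no token renderer for feature ", feature)
  )
}

# pattern(s) whose matches constitute "all mentions" of a feature
feature_patterns <- function(feature) {
  if (feature %in% names(feature_specs())) {
    return(feature_specs()[[feature]]$pattern)
  }
  switch(feature,
    X12 = c(.FRACTION_PATTERN, .FRACTION_FALLBACK),
    ICD = .ICD_PATTERN,
    stop("unknown feature: ", feature)
  )
}

#' Inject a controlled defect into a finding document
#'
#' Realizes the failure modes the extraction contract must handle:
#' `"conflicting_duplicate"` appends a second mention of the feature with a
#' different value (forcing the ambiguous class); `"omission"` deletes every
#' mention of the feature (forcing the empty class); `"x_value"` replaces
#' the feature's value with X (allowed for M, L, V, R only, whose X means
#' "no statement possible"); `"ocr_noise"` substitutes characters at the
#' given per-character rate, by default sparing the truth-critical tokens.
#' Every perturbation is appended to the document's log.
#'
#' @param doc a `finding_document`.
#' @param kind one of `"conflicting_duplicate"`, `"omission"`, `"x_value"`,
#'   `"ocr_noise"`.
#' @param feature target feature (`T,N,M,L,V,R,X12,ICD`; ignored for
#'   `ocr_noise`).
#' @param rate per-character substitution probability (`ocr_noise` only).
#' @param protect spare truth-critical tokens from noise (default `TRUE`).
#' @param seed optional seed; when supplied the perturbation draws from a
#'   private RNG stream, otherwise from the current RNG state (as inside
#'   [generate_corpus()]).
#' @return the perturbed `finding_document` with an extended log.
#' @export
perturb_document <- function(doc, kind, feature = NULL, rate = 0.02,
                             protect = TRUE, seed = NULL) {
  stopifnot(inherits(doc, "finding_document"))
  run <- function(expr) {
    if (is.null(seed)) expr else withr::with_seed(seed, expr)
  }
  run(switch(kind,
    conflicting_duplicate = perturb_duplicate(doc, feature),
    omission = perturb_omission(doc, feature),
    x_value = perturb_x_value(doc, feature),
    ocr_noise = perturb_ocr(doc, rate, protect),
    stop("unknown perturbation kind: ", kind, call. = FALSE)
  ))
}

perturb_duplicate <- function(doc, feature) {
  truth <- doc$truth
  dom <- tnm_domains()
  if (feature %in% names(dom)) {
    alt <- sample(setdiff(dom[[feature]], truth[[feature]]), 1)
    token <- render_token(feature, alt)
  } else if (feature == "X12") {
    alt <- sprintf("(%d/%d)", truth$X2 + 1L, truth$X1 + 3L)
    token <- alt
  } else if (feature == "ICD") {
    alt <- sample(setdiff(icd_lookup()$code, truth$localization_code), 1)
    token <- alt
  } else {
    stop("conflicting_duplicate not defined for feature ", feature, call. = FALSE)
  }
  doc$text <- paste0(doc$text, "\nNachtrag: ", token, ".")
  doc$perturbations <- c(doc$perturbations,
                         list(list(kind = "conflicting_duplicate",
                                   feature = feature, detail = token)))
  doc
}

perturb_omission <- function(doc, feature) {
  for (p in feature_patterns(feature)) {
    doc$text <- gsub(p, "", doc$text, perl = TRUE)
  }
  doc$perturbations <- c(doc$perturbations,
                         list(list(kind = "omission", feature = feature,
                                   detail = "all mentions deleted")))
  doc
}

perturb_x_value <- function(doc, feature) {
  if (!feature %in% X_EMPTY_FEATURES) {
    stop("x_value perturbation is defined only for M, L, V, R ",
         "(X is an ordinary value for T and N)", call. = FALSE)
  }
  doc$text <- gsub(feature_patterns(feature), paste0(feature, "X"),
                   doc$text, perl = TRUE)
  doc$perturbations <- c(doc$perturbations,
                         list(list(kind = "x_value", feature = feature,
                                   detail = paste0(feature, "X"))))
  doc
}

perturb_ocr <- function(doc, rate, protect) {
  check_prob(rate, "rate")
  chars <- strsplit(doc$text, "", fixed = TRUE)[[1]]
  eligible <- grepl("[A-Za-z0-9]", chars)
  if (protect) {
    for (span in truth_token_spans(doc$text)) {
      eligible[span[1]:span[2]] <- FALSE
    }
  }
  idx <- which(eligible & stats::runif(length(chars)) < rate)
  for (i in idx) {
    pool <- if (grepl("[0-9]", chars[i])) 0:9 else letters
    repl <- sample(setdiff(as.character(pool), chars[i]), 1)
    chars[i] <- repl
  }
  doc$text <- paste(chars, collapse = "")
  doc$perturbations <- c(doc$perturbations,
                         list(list(kind = "ocr_noise", feature = NA_character_,
                                   detail = sprintf("rate=%g n_substituted=%d",
                                                    rate, length(idx)))))
  doc
}
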