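# Synthetic registry cohort with latent segment structure: segment-shifted
# numeric attributes, segment-tilted categorical attributes, and therapy
# decisions drawn from sparse segment-specific logistic rules with
# prevalence-calibrated intercepts.

#' Configuration for a synthetic cohort
#'
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @param n_segments number of latent patient segments (default 3).
#' @param missing_rate MCAR per-cell missingness probability of the
#'   pre-treatment attributes.
#' @param prevalence_targets named probabilities of the positive class per
#'   decision. Defaults reflect a strongly imbalanced registry: about 92%
#'   operation-positive and about 2% other-therapy-positive; the remaining
#'   decisions are minority-positive.
#' @param segment_shift standard-deviation shift separating segment means of
#'   the numeric attributes.
#' @param segment_tilt multiplicative boost of each segment's preferred
#'   category of every categorical attribute.
#' @param effect_size standard deviation of the segment-specific rule
#'   coefficients generating the decisions.
#' @param rule_attributes pre-treatment attributes that drive every decision
#'   rule; all others are pure noise with respect to the labels.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2000, seed = 1, n_segments = 3,
                          missing_rate = 0.1,
                          prevalence_targets = c(
                            therapy_intention = 0.35, operation = 0.92,
                            radiation = 0.30, local_chemotherapy = 0.05,
                            systemic_chemotherapy = 0.25, other_therapy = 0.02),
                          segment_shift = 1.5, segment_tilt = 4,
                          effect_size = 2,
                          rule_attributes = c("t_classification",
                                              "n_classification",
                                              "clinical_state")) {
  n_patients <- check_count(n_patients, "n_patients")
  n_segments <- check_count(n_segments, "n_segments")
  check_prob(missing_rate, "missing_rate")
  stopifnot(setequal(names(prevalence_targets), DECISION_NAMES))
  for (d in names(prevalence_targets)) check_prob(prevalence_targets[[d]], d)
  structure(
    list(n_patients = n_patients, seed = as.integer(seed),
         n_segments = n_segments, missing_rate = missing_rate,
         prevalence_targets = prevalence_targets[DECISION_NAMES],
         segment_shift = segment_shift, segment_tilt = segment_tilt,
         effect_size = effect_size, rule_attributes = rule_attributes),
    class = "cohort_config"
  )
}

# realistic location/scale used to put numeric attributes on clinical units
.NUMERIC_UNITS <- list(
  age = c(63, 11), height = c(172, 9), weight = c(76, 14),
  amount_of_alcohol = c(18, 12), pack_years = c(22, 15),
  tumor_number = c(1.3, 0.6), tumor_size = c(28, 12),
  duration_precancerous_lesions = c(6, 5)
)

#' Generate a synthetic patient cohort
#'
#' Each patient draws a latent segment; numeric attributes come from
#' segment-shifted normals (mapped onto clinical units), categorical
#' attributes from segment-tilted multinomials. Each therapy decision is
#' drawn from a logistic rule over the one-hot columns of the configured
#' rule attributes with independent segment-specific coefficients, and an
#' intercept calibrated by root finding so the expected prevalence equals
#' the configured target. Missingness is applied completely at random
#' afterwards. Generator truth (segments, rule coefficients, intercepts) is
#' attached as the `"truth"` attribute.
#'
#' @param config a [cohort_config()].
#' @param schema a [default_schema()] (or compatible).
#' @return data.frame with the 38 attribute columns (numerics and character
#'   categoricals, `NA` = missing), 6 logical decision columns and a
#'   `.segment` provenance column; attribute `"truth"` carries the
#'   generator internals.
#' @export
generate_cohort <- function(config = cohort_config(), schema = default_schema()) {
  stopifnot(inherits(config, "cohort_config"), inherits(schema, "cohort_schema"))
  n <- config$n_patients
  k <- config$n_segments
  attrs <- schema$attributes
  withr::with_seed(config$seed, {
    segment <- sample.int(k, n, replace = TRUE)
    data <- list()
    # segment-conditional attribute distributions
    for (j in seq_len(nrow(attrs))) {
      a <- attrs$name[j]
      if (attrs$kind[j] == "numeric") {
        mu <- stats::rnorm(k) * config$segment_shift
        unit <- .NUMERIC_UNITS[[a]] %||% c(0, 1)
        z <- mu[segment] + stats::rnorm(n)
        data[[a]] <- unit[1] + unit[2] * z
      } else {
        lv <- schema$levels[[a]]
        base <- stats::runif(length(lv), 0.5, 1.5)
        probs <- vapply(seq_len(k), function(s) {
          w <- base
          w[((s + j) %% length(lv)) + 1L] <- w[((s + j) %% length(lv)) + 1L] * config$segment_tilt
          w / sum(w)
        }, numeric(length(lv)))
        data[[a]] <- vapply(seq_len(n), function(i) {
          sample(lv, 1, prob = probs[, segment[i]])
        }, "")
      }
    }
    cohort <- as.data.frame(data, stringsAsFactors = FALSE)
    # decisions from sparse segment-specific logistic rules over the
    # complete (pre-missingness) encoded data
    enc <- encode_cohort(cohort, schema)
    rule_cols <- which(enc$column_map$attribute %in% config$rule_attributes)
    coefficients <- list()
    intercepts <- numeric(length(DECISION_NAMES))
    names(intercepts) <- DECISION_NAMES
    for (d in DECISION_NAMES) {
      beta <- matrix(stats::rnorm(k * length(rule_cols), sd = config$effect_size),
                     nrow = k)
      eta <- rowSums(enc$x[, rule_cols, drop = FALSE] * beta[segment, , drop = FALSE])
      b0 <- calibrate_intercept(eta, config$prevalence_targets[[d]])
      cohort[[d]] <- stats::runif(n) < stats::plogis(eta + b0)
      coefficients[[d]] <- beta
      intercepts[[d]] <- b0
    }
    # MCAR missingness on the pre-treatment attributes only
    if (config$missing_rate > 0) {
      for (a in attrs$name) {
        drop <- stats::runif(n) < config$missing_rate
        cohort[[a]][drop] <- NA
      }
    }
    cohort$.segment <- segment
    attr(cohort, "truth") <- list(
      segment = segment,
      rule_attributes = config$rule_attributes,
      rule_columns = enc$column_map$column[rule_cols],
      coefficients = coefficients,
      intercepts = intercepts
    )
    cohort
  })
}

# intercept b such that mean(plogis(eta + b)) equals the target prevalence
calibrate_intercept <- function(eta, target) {
  if (target <= 0 || target >= 1) {
    stop(sprintf("prevalence target %g unreachable: must lie strictly in (0, 1)",
                 target), call. = FALSE)
  }
  f <- function(b) mean(stats::plogis(eta + b)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf("prevalence target %g unreachable at the configured rule scale",
                 target), call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Write a cohort as CSV plus schema/truth sidecars
#'
#' One row per patient, decision columns as 0/1, missing values as empty
#' cells; the schema and the generator truth go to JSON sidecar files.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path CSV output path; sidecars get `.schema.json` / `.truth.json`
#'   suffixes.
#' @param schema the schema the cohort conforms to.
#' @return invisibly `path`.
#' @export
write_cohort_csv <- function(cohort, path, schema = default_schema()) {
  out <- cohort
  for (d in intersect(DECISION_NAMES, names(out))) {
    out[[d]] <- as.integer(out[[d]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(attributes = schema$attributes, levels = schema$levels,
         decisions = schema$decisions,
         encoded_dimension = schema$encoded_dimension),
    paste0(path, ".schema.json"), auto_unbox = TRUE, digits = NA)
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
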