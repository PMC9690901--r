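# Division-of-Labor decision support: a Central Executive segments the
# encoded cohort (k-means) and maintains one Expert per segment; each Expert
# holds six online therapy-decision classifiers plus six L1 (lasso)
# attribute-importance models. Queries are routed to the nearest centroid.

#' Configuration of the Division-of-Labor system
#'
#' @param n_segments number of patient segments, or `"auto"` to select by
#'   mean silhouette over 2-6 segments.
#' @param base_model classifier type used by Experts and by the standalone
#'   comparison arm of [run_benchmark()]: one of `"prior"`, `"lasso"`,
#'   `"logistic"` (online), `"lpm"`, `"tree"`, `"svm"`.
#' @param l1_grid lasso penalty grid for hyper-parameter search (6
#'   log-spaced values by default).
#' @param cv_outer_folds,cv_inner_folds outer evaluation folds (default 10)
#'   and inner grid-search folds (default 3).
#' @param eta0,sgd_lambda learning-rate scale and L2 regularization of the
#'   online logistic updates.
#' @param overall_weighting weights of the per-decision scores in "overall"
#'   aggregates: `"samples"` (all test samples per task, the default) or
#'   `"positives"` (positive samples per task).
#' @param seed master seed for clustering and fold assignment.
#' @return object of class `dol_config`.
#' @export
dol_config <- function(n_segments = 3, base_model = "logistic",
                       l1_grid = 10^seq(-3, 0, length.out = 6),
                       cv_outer_folds = 10, cv_inner_folds = 3,
                       eta0 = 0.5, sgd_lambda = 1e-4,
                       overall_weighting = c("samples", "positives"),
                       seed = 1) {
  if (!identical(n_segments, "auto")) n_segments <- check_count(n_segments, "n_segments")
  stopifnot(base_model %in% c("prior", "lasso", "logistic", "lpm", "tree", "svm"),
            cv_outer_folds >= 2, cv_inner_folds >= 2, length(l1_grid) >= 1)
  structure(
    list(n_segments = n_segments, base_model = base_model, l1_grid = l1_grid,
         cv_outer_folds = as.integer(cv_outer_folds),
         cv_inner_folds = as.integer(cv_inner_folds),
         eta0 = eta0, sgd_lambda = sgd_lambda,
         overall_weighting = match.arg(overall_weighting),
         seed = as.integer(seed)),
    class = "dol_config"
  )
}

# mean silhouette width of a clustering (on a subsample for large n)
mean_silhouette <- function(x, cluster, max_n = 400) {
  n <- nrow(x)
  idx <- if (n > max_n) seq(1, n, length.out = max_n) else seq_len(n)
  idx <- unique(as.integer(idx))
  d <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
  cl <- cluster[idx]
  sil <- vapply(seq_along(idx), function(i) {
    own <- cl == cl[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(s) mean(d[i, cl == s]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' Fit the Division-of-Labor system on an encoded cohort
#'
#' Clusters the encoded design matrix with seeded k-means, instantiates one
#' Expert per segment, then streams every patient (in data order) to its
#' segment's Expert, which performs one online update of each of its six
#' decision classifiers. After the stream, each Expert refreshes its L1
#' importance model per decision (a lasso fit on the data it accumulated,
#' with the penalty chosen by internal cross-validation). An Expert that saw
#' only one class of a decision falls back to a smoothed prior for that
#' decision.
#'
#' @param x encoded design matrix (from [encode_cohort()]).
#' @param y logical decision matrix (from [decision_matrix()]).
#' @param config a [dol_config()].
#' @param column_map encoding column map, kept for attribute-level
#'   importance aggregation.
#' @param stats encoding statistics, kept so new patients are encoded on
#'   the training scale.
#' @param schema cohort schema for encoding raw patients at predict time.
#' @return object of class `central_executive`.
#' @export
dol_fit <- function(x, y, config = dol_config(), column_map = NULL,
                    stats = NULL, schema = NULL) {
  stopifnot(is.matrix(x), nrow(x) == nrow(y), ncol(y) == length(DECISION_NAMES))
  k <- config$n_segments
  if (identical(k, "auto")) {
    scores <- vapply(2:6, function(kk) {
      cl <- withr::with_seed(config$seed,
                             stats::kmeans(x, centers = kk, nstart = 5,
                                           iter.max = 50))
      mean_silhouette(x, cl$cluster)
    }, numeric(1))
    k <- (2:6)[which.max(scores)]
  }
  if (k > nrow(x)) {
    stop(sprintf("n_segments (%d) exceeds the number of patients (%d)",
                 k, nrow(x)), call. = FALSE)
  }
  km <- withr::with_seed(config$seed,
                         stats::kmeans(x, centers = k, nstart = 5,
                                       iter.max = 50))
  experts <- lapply(seq_len(k), function(s) {
    list(segment_id = s,
         classifiers = stats::setNames(
           rep(list(online_logistic_new(ncol(x), config$eta0, config$sgd_lambda)),
               length(DECISION_NAMES)), DECISION_NAMES),
         importance = NULL, rows = integer(0))
  })
  # stream each patient to its segment's Expert: one online update per decision
  for (i in seq_len(nrow(x))) {
    s <- km$cluster[i]
    xi <- x[i, ]
    for (d in DECISION_NAMES) {
      experts[[s]]$classifiers[[d]] <-
        online_logistic_update(experts[[s]]$classifiers[[d]], xi, y[i, d])
    }
    experts[[s]]$rows <- c(experts[[s]]$rows, i)
  }
  # refresh the per-decision L1 importance models on the accumulated data
  for (s in seq_len(k)) {
    rows <- experts[[s]]$rows
    experts[[s]]$n <- length(rows)
    experts[[s]]$importance <- lapply(stats::setNames(DECISION_NAMES, DECISION_NAMES),
                                      function(d) {
      ys <- y[rows, d]
      if (length(ys) < 12L || min(sum(ys), sum(!ys)) < 3L) {
        # (near-)single-class segment: no importance signal to extract
        return(numeric(ncol(x)))
      }
      fixed_lambda_fit <- function() {
        fit <- glmnet::glmnet(x[rows, , drop = FALSE],
                              factor(ys, levels = c(FALSE, TRUE)),
                              family = "binomial", alpha = 1, lambda = 0.01)
        as.numeric(fit$beta[, 1])
      }
      if (min(sum(ys), sum(!ys)) >= 30L) {
        # enough of both classes for an internal CV over the lasso path
        foldid <- withr::with_seed(derive_seed(config$seed, s),
                                   sample(rep_len(1:3, length(ys))))
        tryCatch({
          fit <- glmnet::cv.glmnet(x[rows, , drop = FALSE],
                                   factor(ys, levels = c(FALSE, TRUE)),
                                   family = "binomial", alpha = 1,
                                   foldid = foldid)
          as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
        }, error = function(e) fixed_lambda_fit())
      } else {
        # too few minority samples for CV folds: fixed moderate penalty
        fixed_lambda_fit()
      }
    })
    experts[[s]]$single_class <- vapply(DECISION_NAMES, function(d) {
      length(unique(y[rows, d])) < 2L
    }, logical(1))
    experts[[s]]$prior <- vapply(DECISION_NAMES, function(d) {
      (sum(y[rows, d]) + 1) / (length(rows) + 2)
    }, numeric(1))
  }
  structure(
    list(centroids = km$centers, experts = experts, config = config,
         column_map = column_map, stats = stats, schema = schema,
         n_features = ncol(x),
         decision_pos = colSums(y), decision_n = rep(nrow(y), ncol(y))),
    class = "central_executive"
  )
}

#' @export
print.central_executive <- function(x, ...) {
  cat(sprintf("Division-of-Labor system: %d segment(s), %d encoded features\n",
              length(x$experts), x$n_features))
  for (e in x$experts) {
    cat(sprintf("  Expert %d: %d patients\n", e$segment_id, e$n))
  }
  invisible(x)
}

# route encoded rows to segments: nearest centroid (Euclidean), ties broken
# by the lowest segment id (which.min returns the first minimum)
route_segments <- function(ce, x) {
  d2 <- vapply(seq_len(nrow(ce$centroids)), function(s) {
    rowSums(sweep(x, 2, ce$centroids[s, ])^2)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) d2 <- matrix(d2, nrow = 1)
  apply(d2, 1, which.min)
}

# probability matrix (n x 6) for encoded rows under the fitted system
dol_prob_matrix <- function(ce, x) {
  seg <- route_segments(ce, x)
  probs <- matrix(NA_real_, nrow(x), length(DECISION_NAMES),
                  dimnames = list(NULL, DECISION_NAMES))
  for (s in unique(seg)) {
    rows <- which(seg == s)
    e <- ce$experts[[s]]
    for (d in DECISION_NAMES) {
      probs[rows, d] <- if (e$single_class[[d]]) {
        e$prior[[d]]
      } else {
        online_logistic_prob(e$classifiers[[d]], x[rows, , drop = FALSE])
      }
    }
  }
  probs
}

#' Predict the six therapy decisions for a patient
#'
#' The patient may be given as a raw attribute list/row (any subset of
#' attributes observed — an all-missing patient is legal and receives
#' prior-informed predictions from the deterministically routed Expert) or
#' as an already-encoded feature vector. Routing goes to the nearest
#' centroid in encoded space; distance ties break toward the lowest segment
#' id.
#'
#' @param ce fitted `central_executive`.
#' @param patient one-row data.frame / named list of attributes, or a
#'   numeric vector of length `n_features`.
#' @return data.frame with columns `decision`, `label`, `probability`,
#'   `segment`.
#' @export
dol_predict <- function(ce, patient) {
  stopifnot(inherits(ce, "central_executive"))
  if (is.numeric(patient) && is.null(dim(patient))) {
    x <- matrix(patient, nrow = 1)
  } else {
    if (is.null(ce$schema) || is.null(ce$stats)) {
      stop("this system was fitted without schema/stats; pass an encoded vector",
           call. = FALSE)
    }
    row <- as.list(patient)
    full <- stats::setNames(vector("list", nrow(ce$schema$attributes)),
                            ce$schema$attributes$name)
    for (a in names(full)) {
      full[[a]] <- if (!is.null(row[[a]]) && !is.na(row[[a]])) row[[a]] else NA
    }
    df <- as.data.frame(full, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(ce$schema$attributes))) {
      a <- ce$schema$attributes$name[j]
      df[[a]] <- if (ce$schema$attributes$kind[j] == "numeric") {
        as.numeric(df[[a]])
      } else {
        as.character(df[[a]])
      }
    }
    x <- encode_cohort(df, ce$schema, stats = ce$stats)$x
  }
  stopifnot(ncol(x) == ce$n_features)
  seg <- route_segments(ce, x)
  probs <- dol_prob_matrix(ce, x)
  data.frame(decision = DECISION_NAMES,
             label = as.vector(probs[1, ] >= 0.5),
             probability = as.vector(probs[1, ]),
             segment = seg[1],
             stringsAsFactors = FALSE)
}

#' Rank patient attributes by importance for the therapy decisions
#'
#' Per decision, the encoded-feature L1 coefficients of every Expert are
#' aggregated to attribute level (sum of absolute coefficients over the
#' attribute's one-hot columns) and averaged over Experts weighted by their
#' sample counts. `"overall"` averages the per-decision attribute scores,
#' weighted by per-task sample counts (all samples by default, positives
#' under `overall_weighting = "positives"`). Scores are returned sorted
#' non-increasingly; only the ranking (not the score scale) is meaningful.
#'
#' @param ce fitted `central_executive` (with a column map).
#' @param decision one of the six decision names or `"overall"`.
#' @return data.frame with columns `attribute`, `score`, sorted by
#'   decreasing score.
#' @export
rank_attributes <- function(ce, decision = "overall") {
  if (!inherits(ce, "central_executive")) {
    stop("`ce` must be a fitted central_executive", call. = FALSE)
  }
  if (is.null(ce$column_map)) {
    stop("system was fitted without a column map; refit with `column_map`",
         call. = FALSE)
  }
  stopifnot(decision %in% c(DECISION_NAMES, "overall"))
  attr_names <- unique(ce$column_map$attribute)
  per_decision <- function(d) {
    weights <- vapply(ce$experts, `[[`, numeric(1), "n")
    coefs <- vapply(ce$experts, function(e) abs(e$importance[[d]]),
                    numeric(ce$n_features))
    pooled <- drop(coefs %*% (weights / sum(weights)))
    vapply(attr_names, function(a) {
      sum(pooled[ce$column_map$attribute == a])
    }, numeric(1))
  }
  if (decision == "overall") {
    w <- if (ce$config$overall_weighting == "positives") {
      ce$decision_pos
    } else {
      ce$decision_n
    }
    w <- w / sum(w)
    scores <- Reduce(`+`, Map(function(d, wi) per_decision(d) * wi,
                              DECISION_NAMES, as.list(w)))
  } else {
    scores <- per_decision(decision)
  }
  out <- data.frame(attribute = attr_names, score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$attribute), , drop = FALSE]
}
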