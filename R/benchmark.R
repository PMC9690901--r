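# Cross-validated F1 benchmark: baseline and standard classifiers, standalone
# and wrapped in the Division-of-Labor framework, over the six therapy
# decisions. Outer k-fold evaluation with an inner grid search per training
# fold; per-task F1 of the positive class on the pooled outer test folds.

#' F1 score of the positive class
#'
#' Convention: when positives exist but no positive predictions were made,
#' F1 is 0 (this reproduces the characteristic zeros of a majority-negative
#' prior classifier); when neither positives nor positive predictions exist
#' the score is vacuously 1.
#'
#' @param truth,pred logical vectors.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  if (tp + fp == 0) {
    return(if (tp + fn == 0) 1 else 0)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# ---- base-model registry -------------------------------------------------

# hyper-parameter grid of one model under a config; NULL = nothing to tune
model_grid <- function(model, config) {
  switch(model,
    random = NULL,
    prior = NULL,
    lpm = NULL,
    lasso = data.frame(lambda = config$l1_grid),
    logistic = data.frame(lambda = config$l1_grid),
    tree = data.frame(depth = 2:10),
    svm = data.frame(cost = 10^seq(-2, 2, length.out = 5)),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# fit one base model for one decision; returns an object for predict_base()
fit_base <- function(model, x, y, params = NULL, seed = 1) {
  if (model != "random" && length(unique(y)) < 2L) {
    # degenerate training set: fall back to the prior
    return(list(type = "prior", majority = mean(y) >= 0.5))
  }
  switch(model,
    random = list(type = "random", seed = seed),
    prior = list(type = "prior", majority = mean(y) >= 0.5),
    lasso = list(type = "lasso",
                 fit = glmnet::glmnet(x, as.numeric(y), family = "gaussian",
                                      alpha = 1, lambda = params$lambda,
                                      standardize = FALSE)),
    logistic = list(type = "logistic",
                    fit = online_logistic_fit(x, as.numeric(y),
                                              eta0 = 0.5,
                                              lambda = params$lambda)),
    lpm = {
      cf <- stats::lm.fit(cbind(1, x), as.numeric(y))$coefficients
      cf[is.na(cf)] <- 0
      list(type = "lpm", coef = cf)
    },
    tree = {
      df <- as.data.frame(x)
      colnames(df) <- paste0("f", seq_len(ncol(x)))
      df$.y <- factor(y, levels = c(FALSE, TRUE))
      list(type = "tree",
           fit = rpart::rpart(.y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                maxdepth = params$depth, cp = 1e-4,
                                minsplit = 10, xval = 0)))
    },
    svm = list(type = "svm",
               fit = withr::with_seed(seed,
                 e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                            kernel = "linear", cost = params$cost,
                            scale = FALSE))),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# predicted labels of a fitted base model on new rows
predict_base <- function(obj, x) {
  switch(obj$type,
    random = withr::with_seed(obj$seed, stats::runif(nrow(x)) < 0.5),
    prior = rep(obj$majority, nrow(x)),
    lasso = drop(stats::predict(obj$fit, x)) >= 0.5,
    logistic = online_logistic_prob(obj$fit, x) >= 0.5,
    lpm = drop(cbind(1, x) %*% obj$coef) >= 0.5,
    tree = {
      df <- as.data.frame(x)
      colnames(df) <- paste0("f", seq_len(ncol(x)))
      stats::predict(obj$fit, df, type = "class") == "TRUE"
    },
    svm = stats::predict(obj$fit, x) == "TRUE",
    stop("unknown fit type: ", obj$type)
  )
}

# ---- Division-of-Labor wrapping -----------------------------------------

# fit one base model per training-set cluster; predict routes to centroids
fit_dol_wrapped <- function(model, x, y, k, params, seed) {
  k <- min(k, nrow(x))
  km <- withr::with_seed(seed, stats::kmeans(x, centers = k, nstart = 3,
                                             iter.max = 30))
  fits <- lapply(seq_len(k), function(s) {
    rows <- km$cluster == s
    fit_base(model, x[rows, , drop = FALSE], y[rows], params,
             seed = derive_seed(seed, s))
  })
  list(centroids = km$centers, fits = fits)
}

predict_dol_wrapped <- function(obj, x) {
  d2 <- vapply(seq_len(nrow(obj$centroids)), function(s) {
    rowSums(sweep(x, 2, obj$centroids[s, ])^2)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) d2 <- matrix(d2, nrow = 1)
  seg <- apply(d2, 1, which.min)
  out <- logical(nrow(x))
  for (s in unique(seg)) {
    rows <- seg == s
    out[rows] <- predict_base(obj$fits[[s]], x[rows, , drop = FALSE])
  }
  out
}

# ---- cross-validated benchmark ------------------------------------------

# inner grid search: pick the grid row maximizing pooled inner-fold F1
search_params <- function(model, variant, x, y, grid, config, seed) {
  if (is.null(grid) || nrow(grid) == 1L) {
    return(if (is.null(grid)) NULL else grid[1, , drop = FALSE])
  }
  inner <- withr::with_seed(seed, sample(rep_len(seq_len(config$cv_inner_folds),
                                                 length(y))))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    pred <- logical(length(y))
    for (f in seq_len(config$cv_inner_folds)) {
      tr <- inner != f
      obj <- if (variant == "dol") {
        fit_dol_wrapped(model, x[tr, , drop = FALSE], y[tr],
                        config$n_segments, grid[g, , drop = FALSE],
                        derive_seed(seed, f))
      } else {
        fit_base(model, x[tr, , drop = FALSE], y[tr],
                 grid[g, , drop = FALSE], derive_seed(seed, f))
      }
      pred[!tr] <- if (variant == "dol") {
        predict_dol_wrapped(obj, x[!tr, , drop = FALSE])
      } else {
        predict_base(obj, x[!tr, , drop = FALSE])
      }
    }
    f1_score(y, pred)
  }, numeric(1))
  grid[which.max(scores), , drop = FALSE]
}

#' Run the cross-validated F1 benchmark
#'
#' For every requested model and variant (standalone and wrapped in the
#' Division-of-Labor framework), runs outer k-fold cross-validation per
#' therapy decision: encoding statistics are fitted on each training fold,
#' hyper-parameters are chosen by an inner grid search (3-fold by default)
#' on that training fold, the chosen model predicts the held-out fold, and
#' the per-task F1 of the positive class is computed on the pooled outer
#' test predictions. The overall column averages the six task scores
#' weighted by per-task test-sample counts (see `overall_weighting` in
#' [dol_config()]). The random guesser has no Division-of-Labor variant.
#'
#' @param cohort data.frame with attribute and decision columns.
#' @param config a [dol_config()]; `cv_outer_folds`, `cv_inner_folds`,
#'   `l1_grid`, `n_segments` and `seed` are honored.
#' @param models subset of `c("random","prior","lasso","logistic","lpm",
#'   "tree","svm")`.
#' @param variants subset of `c("standalone", "dol")`.
#' @param schema cohort schema.
#' @return object of class `benchmark_table`: data.frame with `model`,
#'   `variant`, the six task columns and `overall`.
#' @export
run_benchmark <- function(cohort, config = dol_config(),
                          models = c("random", "prior", "lasso", "logistic",
                                     "lpm", "tree", "svm"),
                          variants = c("standalone", "dol"),
                          schema = default_schema()) {
  y <- decision_matrix(cohort)
  n <- nrow(cohort)
  folds <- withr::with_seed(config$seed,
                            sample(rep_len(seq_len(config$cv_outer_folds), n)))
  arms <- list()
  for (m in models) {
    for (v in variants) {
      if (m == "random" && v == "dol") next
      arms[[paste(m, v, sep = "_")]] <- list(model = m, variant = v)
    }
  }
  pred <- lapply(arms, function(a) {
    matrix(NA, n, length(DECISION_NAMES), dimnames = list(NULL, DECISION_NAMES))
  })
  single_class_folds <- character()
  for (f in seq_len(config$cv_outer_folds)) {
    tr <- folds != f
    enc_tr <- encode_cohort(cohort[tr, , drop = FALSE], schema)
    enc_te <- encode_cohort(cohort[!tr, , drop = FALSE], schema,
                            stats = enc_tr$stats)
    for (d in DECISION_NAMES) {
      ytr <- y[tr, d]
      if (length(unique(y[!tr, d])) < 2L) {
        single_class_folds <- c(single_class_folds, paste(d, f, sep = "/"))
      }
      for (arm_name in names(arms)) {
        a <- arms[[arm_name]]
        seed_f <- derive_seed(config$seed, f * 100 + match(d, DECISION_NAMES))
        grid <- model_grid(a$model, config)
        best <- search_params(a$model, a$variant, enc_tr$x, ytr, grid,
                              config, seed_f)
        obj <- if (a$variant == "dol") {
          fit_dol_wrapped(a$model, enc_tr$x, ytr, config$n_segments, best,
                          seed_f)
        } else {
          fit_base(a$model, enc_tr$x, ytr, best, seed_f)
        }
        pred[[arm_name]][!tr, d] <- if (a$variant == "dol") {
          predict_dol_wrapped(obj, enc_te$x)
        } else {
          predict_base(obj, enc_te$x)
        }
      }
    }
  }
  rows <- lapply(names(arms), function(arm_name) {
    a <- arms[[arm_name]]
    scores <- vapply(DECISION_NAMES, function(d) {
      f1_score(y[, d], as.logical(pred[[arm_name]][, d]))
    }, numeric(1))
    w <- if (config$overall_weighting == "positives") colSums(y) else rep(n, 6)
    overall <- sum(scores * w) / sum(w)
    data.frame(model = a$model, variant = a$variant, t(scores),
               overall = overall, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "single_class_test_folds") <- single_class_folds
  attr(out, "predictions") <- pred
  attr(out, "labels") <- y
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(format_benchmark_table(x), sep = "\n")
  invisible(x)
}

#' Format a benchmark table as aligned text
#'
#' Rows are models (with " DoL" appended for the wrapped variant), columns
#' the six therapy decisions plus the weighted overall score.
#'
#' @param x a `benchmark_table`.
#' @return character vector of lines.
#' @export
format_benchmark_table <- function(x) {
  label <- ifelse(x$variant == "dol", paste(x$model, "DoL"), x$model)
  header <- sprintf("%-16s %s", "Model",
                    paste(sprintf("%9s", c(abbreviate(DECISION_NAMES, 9), "overall")),
                          collapse = " "))
  body <- vapply(seq_len(nrow(x)), function(i) {
    sprintf("%-16s %s", label[i],
            paste(sprintf("%9.3f",
                          as.numeric(x[i, c(DECISION_NAMES, "overall")])),
                  collapse = " "))
  }, "")
  c(header, body)
}

#' Write a benchmark table as CSV
#'
#' @param x a `benchmark_table`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_benchmark_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
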