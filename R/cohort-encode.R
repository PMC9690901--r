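# One-hot / standardized encoding of a cohort into the 160-column design
# matrix, with an invertible column map and principled missing-data
# handling: a missing categorical becomes an all-zero block, a missing
# numeric the training mean — so a patient with no attributes at all still
# encodes to a well-defined vector.

#' Encode a cohort into the design matrix
#'
#' Categorical attributes are one-hot expanded (one column per category,
#' row-sum 1 when observed, all-zero when missing); numeric attributes are
#' standardized by training-set mean and standard deviation, with missing
#' values imputed at the training mean (i.e. 0 after standardization). Pass
#' the `stats` of a previously encoded training set to encode new patients
#' on the same scale.
#'
#' @param cohort data.frame with the schema's attribute columns (decision or
#'   provenance columns are ignored).
#' @param schema a `cohort_schema`.
#' @param stats optional training statistics (`$mean`, `$sd` per numeric
#'   attribute) from an earlier encoding.
#' @return list with `x` (numeric matrix, `encoded_dimension` columns),
#'   `column_map` (data.frame: column, attribute, category), `stats`.
#' @export
encode_cohort <- function(cohort, schema = default_schema(), stats = NULL) {
  stopifnot(inherits(schema, "cohort_schema"))
  attrs <- schema$attributes
  n <- nrow(cohort)
  blocks <- list()
  map <- list()
  if (is.null(stats)) {
    stats <- list(mean = list(), sd = list())
    fit_stats <- TRUE
  } else {
    fit_stats <- FALSE
  }
  for (j in seq_len(nrow(attrs))) {
    a <- attrs$name[j]
    v <- cohort[[a]]
    if (is.null(v)) stop("cohort lacks attribute column '", a, "'", call. = FALSE)
    if (attrs$kind[j] == "numeric") {
      v <- as.numeric(v)
      if (fit_stats) {
        m <- mean(v, na.rm = TRUE)
        s <- stats::sd(v, na.rm = TRUE)
        if (!is.finite(m)) m <- 0
        if (!is.finite(s) || s == 0) s <- 1
        stats$mean[[a]] <- m
        stats$sd[[a]] <- s
      }
      z <- (v - stats$mean[[a]]) / stats$sd[[a]]
      z[is.na(z)] <- 0 # training-mean imputation
      blocks[[a]] <- matrix(z, ncol = 1, dimnames = list(NULL, a))
      map[[a]] <- data.frame(column = a, attribute = a,
                             category = NA_character_, stringsAsFactors = FALSE)
    } else {
      lv <- schema$levels[[a]]
      bad <- !is.na(v) & !v %in% lv
      if (any(bad)) {
        stop(sprintf("unknown category '%s' for attribute '%s'",
                     v[which(bad)[1]], a), call. = FALSE)
      }
      block <- matrix(0, n, length(lv),
                      dimnames = list(NULL, paste0(a, "=", lv)))
      idx <- match(v, lv)
      obs <- which(!is.na(idx))
      block[cbind(obs, idx[obs])] <- 1
      blocks[[a]] <- block
      map[[a]] <- data.frame(column = colnames(block), attribute = a,
                             category = lv, stringsAsFactors = FALSE)
    }
  }
  x <- do.call(cbind, blocks)
  column_map <- do.call(rbind, map)
  rownames(column_map) <- NULL
  stopifnot(ncol(x) == schema$encoded_dimension)
  list(x = x, column_map = column_map, stats = stats)
}

#' Extract the decision label matrix of a cohort
#'
#' @param cohort data.frame from [generate_cohort()].
#' @return logical matrix, one column per decision.
#' @export
decision_matrix <- function(cohort) {
  missing <- setdiff(DECISION_NAMES, names(cohort))
  if (length(missing)) {
    stop("cohort lacks decision columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- vapply(DECISION_NAMES, function(d) as.logical(cohort[[d]]),
              logical(nrow(cohort)))
  colnames(m) <- DECISION_NAMES
  m
}
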