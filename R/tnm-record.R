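#' Value domains of the TNM staging parameters
#'
#' The admissible values for each rule-extracted staging parameter, taken
#' from the colorectal TNM classification: T (primary tumor extent),
#' N (regional lymph nodes), M (distant metastasis), L (lymphatic invasion),
#' V (venous invasion) and R (residual tumor after resection). X encodes
#' "no statement possible".
#'
#' @return named list of character vectors, one per parameter.
#' @export
tnm_domains <- function() {
  list(
    T = c("is", "0", "1", "2", "3", "4", "4a", "4b", "X"),
    N = c("0", "1", "1a", "1b", "1c", "2", "2a", "2b", "X"),
    M = c("0", "1", "1a", "1b", "1c", "X"),
    L = c("0", "1", "X"),
    V = c("0", "1", "2", "X"),
    R = c("0", "1", "2", "X")
  )
}

# features whose X value means "no medical statement" (class 3 on extraction)
X_EMPTY_FEATURES <- c("M", "L", "V", "R")

# the ten features scored by the evaluation module
ALL_FEATURES <- c("T", "N", "M", "L", "V", "R", "X1", "X2", "ICD", "NEO")

#' Construct a ground-truth staging record
#'
#' Bundles the staging values carried by one pathology finding: the six TNM
#' descriptors, the lymph-node counts X1 (nodes removed) and X2 (nodes
#' affected), the neoadjuvant-therapy flag and the ICD-10 localization code.
#' All values are validated against [tnm_domains()]; X2 must not exceed X1.
#'
#' @param T,N,M,L,V,R staging values as character scalars (see [tnm_domains()]).
#' @param X1 number of lymph nodes removed (non-negative integer).
#' @param X2 number of lymph nodes affected by tumor; at most `X1`.
#' @param neoadjuvant logical; was neoadjuvant therapy given?
#' @param localization_code ICD-10 code string (e.g. `"C18.7"`) or `NA`.
#' @return an object of class `tnm_record` (a named list).
#' @examples
#' tnm_record(T = "3", N = "1a", M = "0", L = "1", V = "0", R = "0",
#'            X1 = 25, X2 = 2, neoadjuvant = TRUE, localization_code = "C20")
#' @export
tnm_record <- function(T, N, M, L, V, R, X1, X2, neoadjuvant,
                       localization_code = NA_character_) {
  dom <- tnm_domains()
  vals <- list(T = T, N = N, M = M, L = L, V = V, R = R)
  for (f in names(vals)) {
    v <- as.character(vals[[f]])
    if (length(v) != 1L || !(v %in% dom[[f]])) {
      stop(sprintf("value '%s' for %s outside domain {%s}",
                   vals[[f]], f, paste(dom[[f]], collapse = ",")), call. = FALSE)
    }
  }
  X1 <- check_count(X1, "X1", positive = FALSE)
  X2 <- check_count(X2, "X2", positive = FALSE)
  if (X2 > X1) stop("X2 (nodes affected) must not exceed X1 (nodes removed)", call. = FALSE)
  stopifnot(is.logical(neoadjuvant), length(neoadjuvant) == 1L, !is.na(neoadjuvant))
  if (!is.na(localization_code)) {
    localization_code <- toupper(as.character(localization_code))
  }
  structure(
    list(T = as.character(T), N = as.character(N), M = as.character(M),
         L = as.character(L), V = as.character(V), R = as.character(R),
         X1 = X1, X2 = X2, neoadjuvant = neoadjuvant,
         localization_code = localization_code),
    class = "tnm_record"
  )
}

#' @export
print.tnm_record <- function(x, ...) {
  cat(sprintf("TNM record: T%s N%s (%d/%d) M%s L%s V%s R%s  neoadjuvant=%s  ICD=%s\n",
              x$T, x$N, x$X2, x$X1, x$M, x$L, x$V, x$R,
              x$neoadjuvant, x$localization_code))
  invisible(x)
}

# truth value of a record for a scored feature, as a character scalar
truth_value <- function(record, feature) {
  switch(feature,
    T = record$T, N = record$N, M = record$M, L = record$L,
    V = record$V, R = record$R,
    X1 = as.character(record$X1), X2 = as.character(record$X2),
    ICD = record$localization_code,
    NEO = as.character(record$neoadjuvant),
    stop("unknown feature: ", feature)
  )
}
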