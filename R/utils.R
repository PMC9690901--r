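# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministically fans one master seed out to per-component seeds so a
#' single seed reproduces an entire pipeline run. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), index >= 0)
  as.integer((as.double(master) * 7919 + as.double(index) * 104729 + 17) %% 2147483647)
}

# assert a probability argument lies in [0, 1]
check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(p)
}

check_count <- function(n, name, positive = TRUE) {
  ok <- is.numeric(n) && length(n) == 1L && !is.na(n) && n == floor(n) &&
    (if (positive) n >= 1 else n >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(n))
}
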