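#' Evaluate code under a temporary RNG seed
#'
#' With `seed = NULL` the expression runs on the ambient RNG stream (so a
#' caller that has already seeded the session controls everything);
#' otherwise the stream is seeded locally and restored afterwards.
#'
#' @param seed integer or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# single place for the characters treated as unambiguous states
DNA_STATES <- c("A", "C", "G", "T")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
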