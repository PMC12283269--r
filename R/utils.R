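#' @keywords internal
"_PACKAGE"

#' @useDynLib pascl, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Seed handling: every stochastic entry point takes an integer seed and runs
# under a locally restored RNG state, with fixed RNG kinds so results do not
# depend on the session's RNGkind().
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result a valid 32-bit integer. Streams decouple e.g. per-epoch shuffles
# from weight initialisation.
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.double(p)
    h <- (h * 69069 + v * 2654435761 + 12345) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("x", "y", "label", "TP", "TN", "FP", "FN"))

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
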