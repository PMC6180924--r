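# Internal helpers shared across modules.

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage index to a new
#' seed, so that one top-level seed drives every source of randomness in a
#' pipeline run while keeping stages decoupled.
#'
#' @param seed Integer global seed.
#' @param k Integer stage index (>= 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k), length(k) == 1)
  as.integer((as.double(seed) + 7919 * as.double(k)) %% 2147483647)
}

# Seed the RNG only when a seed is supplied.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# FNV-1a hash of a character scalar, as 8 hex digits; used to stamp output
# files with a provenance fingerprint of the serialized configuration.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive_triple <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3 || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a positive numeric triple", what), call. = FALSE)
  }
  invisible(as.double(x))
}
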