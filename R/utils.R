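#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from a single integer seed. Independent
#' stages (simulation, permutation testing, template construction, ...) draw
#' from named substreams so that re-running one stage does not perturb another.
#' The substream seed is a deterministic 31-bit hash of the master seed and the
#' stream name.
#'
#' @param seed integer master seed.
#' @param name character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "simulation")
#' substream_seed(1, "permutation")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(name)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used to tag result bundles with a configuration fingerprint.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), code) + 2^30 # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Frobenius norm.
fnorm <- function(x) sqrt(sum(x^2))

# Stop with a consistent error class so tests can assert on failures.
gfp_stop <- function(..., class = "gradfp_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    gfp_stop(what, " must be a numeric matrix")
  }
  if (!all(is.finite(x))) {
    gfp_stop(what, " contains non-finite values")
  }
  invisible(x)
}
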