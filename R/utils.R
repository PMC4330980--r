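#' Derive a reproducible child seed from a base seed
#'
#' Expands one user-supplied seed into independent per-component streams by
#' a small counter-based integer hash, so that adding a component (e.g. one
#' more replicate) never perturbs the streams of the others. Results stay
#' below 2^31 and are deterministic across platforms.
#'
#' @param baseSeed single integer seed.
#' @param ... one or more non-negative integer counters identifying the
#'   stream (replicate index, cell index, purpose code, ...).
#' @return single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, 1, 2) != deriveSeed(1, 2, 1)
#' @export
deriveSeed <- function(baseSeed, ...) {
  ctrs <- c(...)
  stopifnot(length(baseSeed) == 1L, is.finite(baseSeed))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(baseSeed) %% m
  for (ctr in ctrs) {
    # splitmix-style mixing kept within double-exact integer range
    h <- (h * 48271 + as.double(ctr) * 16807 + 12345) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h)
}

stopInvalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
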