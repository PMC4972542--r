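#' Derive a child seed from a root seed and a key path
#'
#' Deterministic counter-based splitting of one root seed into independent
#' streams. Every stochastic stage of the pipeline (panel construction, trial
#' noise, connectivity, train/test splits) seeds its own stream through this
#' function, so e.g. the identity of odor panel 7 does not depend on how many
#' random draws earlier panels consumed.
#'
#' @param seed Integer root seed.
#' @param ... Integer or single-string keys identifying the stream
#'   (e.g. `"panel", 3, 12`).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' child_seed(1, "panel", 3)
#' @export
child_seed <- function(seed, ...) {
  keys <- c(list(seed), list(...))
  m <- 2147483629 # prime below 2^31; keeps intermediate products < 2^53
  h <- 17
  for (k in keys) {
    if (is.character(k)) {
      stopifnot(length(k) == 1L)
      v <- utf8ToInt(k)
      k <- sum(v * seq_along(v)) %% m
    }
    if (length(k) != 1L || !is.finite(k)) {
      stop("seed keys must be finite scalars or single strings")
    }
    h <- (h * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(h + 1)
}
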