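#' Derive a named substream seed from a root seed
#'
#' Every stochastic stage of the pipeline (climate, gcm, species, catalogue,
#' bootstrap, scenario draws) seeds its own RNG with a value derived
#' deterministically from the root seed and a stage name, so stages are
#' independently reproducible and inserting a stage never perturbs another.
#'
#' The derivation hashes the stream name (Horner scheme) and mixes it with the
#' seed modulo 2^31 - 1; arithmetic stays exact in doubles.
#'
#' @param seed Root integer seed.
#' @param stream Stage name, e.g. `"climate"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m + h) %% m
  s <- (s * 48271) %% m        # Lehmer step; 48271 * (2^31) < 2^53, exact
  as.integer(s %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
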