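#' Derive a child seed from a root seed and a stream key
#'
#' All stochastic operations in the package draw their randomness from a child
#' stream derived from a single root seed and a short string key naming the
#' operation (e.g. `"founders"`, `"meiosis/cycle1"`). This makes partial reruns
#' reproducible: the same root seed always yields the same founder set no matter
#' how many downstream operations were re-executed in between.
#'
#' The key is hashed with a 31-multiplier polynomial rolling hash modulo
#' 2^31 - 1 and folded into the root seed; the result is always a valid
#' 32-bit integer seed.
#'
#' @param seed integer root seed.
#' @param key character stream key.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key), length(key) == 1)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Evaluate an expression under a derived seed, restoring RNG state
#' @param seed integer root seed.
#' @param key character stream key.
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, key))
  expr
}
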