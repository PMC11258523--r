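# Named random streams.
#
# Every stochastic stage (tie-breaking, simulation, Monte Carlo subsampling)
# draws from its own stream so that recomputing one stage never shifts the
# draws of another. A stream is a saved .Random.seed state; stream_eval()
# swaps it in, runs code, and saves it back, restoring the caller's RNG
# state afterwards.

ensure_rng <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  invisible(NULL)
}

save_seed <- function() {
  ensure_rng()
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

restore_seed <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

# Create a stream initialised from an integer seed.
rng_stream <- function(seed) {
  prev <- save_seed()
  on.exit(restore_seed(prev))
  set.seed(as.integer(seed))
  s <- new.env(parent = emptyenv())
  s$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  s
}

# Evaluate `code` under the stream's RNG state; advances the stream.
stream_eval <- function(stream, code) {
  prev <- save_seed()
  restore_seed(stream$state)
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    restore_seed(prev)
  })
  code
}

#' Derive a child seed deterministically from a parent seed and a tag
#'
#' Child seeds keep independently recomputable stages (for example each
#' leave-one-out reference standard) on stable streams: adding or removing one
#' stage never shifts another stage's random draws. The result is always a
#' positive integer below 2^31.
#'
#' @param seed integer parent seed.
#' @param tag character scalar (or vector, concatenated) naming the stage.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "clips")
#' @export
derive_seed <- function(seed, tag) {
  m <- 2147483587 # large prime < 2^31
  h <- 0
  for (ch in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(((as.numeric(seed) %% m) * 69069 + h) %% m + 1)
}

# Run `code` with a temporary seed (NULL = use current RNG, do not restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  prev <- save_seed()
  on.exit(restore_seed(prev))
  set.seed(as.integer(seed))
  code
}
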