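# Independent, named RNG streams on top of R's generator. Each stream is a
# saved `.Random.seed` state; drawing from a stream swaps the state in,
# evaluates, and saves it back. Stream seeds are derived from one master seed
# by a documented splitter, so a run is fully determined by (config, seed)
# while modules (genome, crypt, histone stochastics, damage) stay decoupled:
# draws on one stream never move another.

STREAM_NAMES <- c("genome", "crypt", "histone", "damage")

#' Create independent named RNG streams from a master seed
#'
#' @param master_seed integer master seed.
#' @param names stream names.
#' @return An environment mapping stream name to a saved RNG state.
#' @export
rng_streams <- function(master_seed, names = STREAM_NAMES) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  streams <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(seeds[i])
    assign(names[i], get(".Random.seed", globalenv()), envir = streams)
  }
  streams
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Evaluate an expression under a named RNG stream
#'
#' @param streams an environment from [rng_streams()].
#' @param name stream name.
#' @param expr expression drawing random numbers.
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    restore_rng(old)
  })
  expr
}
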