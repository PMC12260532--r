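## Named RNG streams derived from one master seed. Each named purpose
## (mutation, selection, founders, ...) carries its own saved .Random.seed,
## so adding draws to one stream never shifts another and whole runs are
## reproducible from the master seed alone.

.stream_offsets <- c(founders = 1L, mutation = 2L, selection = 3L,
                     surrogate = 4L, misc = 5L)

#' Create named RNG streams from a master seed
#'
#' @param seed master seed (integer).
#' @param streamNames stream names to create.
#' @return an environment mapping stream name to a saved RNG state; pass to
#'   [withStream()].
#' @keywords internal
#' @export
rngStreams <- function(seed, streamNames = names(.stream_offsets)) {
  env <- new.env(parent = emptyenv())
  old <- .save_rng()
  on.exit(.restore_rng(old))
  for (nm in streamNames) {
    off <- if (nm %in% names(.stream_offsets)) .stream_offsets[[nm]]
           else (sum(utf8ToInt(nm)) %% 1000L) + 10L
    ## keep derived seeds positive and well below 2^31
    sub <- (as.numeric(seed) * 7919 + off * 104729) %% 2147483629
    set.seed(as.integer(sub))
    assign(nm, .Random.seed, envir = env)
  }
  env
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under one named stream
#'
#' Swaps the stream's RNG state in, evaluates `expr`, and saves the advanced
#' state back, leaving the global RNG untouched.
#'
#' @param streams environment from [rngStreams()].
#' @param name stream name.
#' @param expr expression to evaluate.
#' @keywords internal
#' @export
withStream <- function(streams, name, expr) {
  if (!exists(name, envir = streams, inherits = FALSE))
    stop(sprintf("no RNG stream named '%s'", name))
  old <- .save_rng()
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    .restore_rng(old)
  })
  expr
}

## snapshot / restore all stream states (for checkpointing)
.streams_state <- function(streams)
  mget(ls(streams), envir = streams)

.streams_from_state <- function(state) {
  env <- new.env(parent = emptyenv())
  for (nm in names(state)) assign(nm, state[[nm]], envir = env)
  env
}
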