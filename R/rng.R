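# Named independent random streams.
#
# Every replica owns its own stream and the exchange scheduler owns one
# more, so a full run is bit-reproducible from a single master seed and
# no two replicas ever share randomness.  A stream is an environment
# holding a saved .Random.seed; with_stream() swaps it in around an
# expression and captures the advanced state on exit.

#' Create an independent random stream
#'
#' @param seed integer seed (< 2^31).
#' @return an object of class \code{rng_stream}.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- .get_global_seed()
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  .set_global_seed(old)
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' The global RNG state is saved, the stream state swapped in, the
#' expression evaluated, and the advanced state written back to the
#' stream.  The caller's RNG state is untouched.
#'
#' @param stream an \code{rng_stream}.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .get_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .set_global_seed(old)
  })
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic, collision-avoiding map used to hand each replica (and
#' the exchange scheduler) its own stream; results stay below 2^31.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 1000003
  as.integer((m * 7919 + as.double(index) * 104729 + 17) %% 2147483587) + 1L
}

.get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.set_global_seed <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(NULL)
}
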