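# RNG stream helpers. Streams isolate independent randomness sources
# (parameter init, data order, policy noise, bbox jitter) so that, e.g.,
# MT training with lambda = 1 consumes policy-stream draws without
# perturbing the data-order stream, and its trajectory is bit-identical
# to FT training.

#' Create an independent RNG stream
#'
#' @param seed integer seed.
#' @return an environment holding a private `.Random.seed` state; pass it
#'   to [withStream()].
#' @export
newRngStream <- function(seed) {
  s <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  s
}

#' Evaluate an expression under an RNG stream
#'
#' Swaps the stream's state in, evaluates `expr`, records the advanced
#' state back into the stream, and restores the caller's RNG untouched.
#'
#' @param stream a stream from [newRngStream()].
#' @param expr expression to evaluate.
#' @export
withStream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# evaluate expr under a fixed seed without disturbing the global RNG
withSeed <- function(seed, expr) {
  stream <- newRngStream(seed)
  withStream(stream, expr)
}

#' Tight bounding box of a binary mask
#'
#' @param mask binary matrix (rows = y, columns = x).
#' @return integer (x0, y0, x1, y1), 0-based inclusive corners.
#' @export
tightBbox <- function(mask) {
  pos <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("mask is empty; no bounding box exists")
  c(x0 = min(pos[, 2]) - 1L, y0 = min(pos[, 1]) - 1L,
    x1 = max(pos[, 2]) - 1L, y1 = max(pos[, 1]) - 1L)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
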