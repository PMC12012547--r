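#' Wrap an angle to (-pi, pi]
#'
#' Angles are measured counter-clockwise from +x in radians; all headings and
#' heading errors in the package live on the half-open interval (-pi, pi].
#'
#' @param theta numeric vector of angles (rad).
#' @return angles wrapped to (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact odd multiples of pi to -pi; the convention is +pi
  w[w <= -pi] <- pi
  w
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}

#' Independent per-fly random number streams
#'
#' Builds `n + 1` L'Ecuyer-CMRG streams from a single integer seed: stream 0
#' for environment noise (e.g. the pushable ball) and streams `1..n` for the
#' individual flies. Adding a fly extends the list without perturbing any
#' existing stream, so simulations are reproducible fly-by-fly.
#'
#' @param seed integer seed.
#' @param n number of fly streams.
#' @return an environment holding `.Random.seed` vectors under names
#'   `"0", "1", ..., "n"`; pass it to [with_stream()] to draw from one stream.
#' @export
make_rng_streams <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 0)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- new.env(parent = emptyenv())
  assign("0", s, envir = streams)
  if (n > 0) {
    for (i in seq_len(n)) {
      s <- parallel::nextRNGStream(s)
      assign(as.character(i), s, envir = streams)
    }
  }
  streams
}

#' Evaluate an expression on one RNG stream
#'
#' Positions the global RNG on stream `id` of a [make_rng_streams()]
#' environment, evaluates `expr`, and writes the advanced stream state back so
#' the next draw from the same stream continues where it left off.
#'
#' @param streams stream environment from [make_rng_streams()].
#' @param id stream id (0 = environment, 1..n = flies).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(streams, id, expr) {
  key <- as.character(id)
  assign(".Random.seed", get(key, envir = streams), envir = globalenv())
  res <- expr
  assign(key, get(".Random.seed", envir = globalenv()), envir = streams)
  res
}
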