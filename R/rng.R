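#' Seedable, labelled random-number streams
#'
#' Every game subsystem draws from its own stream so that adding or removing
#' one game never perturbs the draws seen by another. A stream is identified
#' by a `(master seed, label)` pair; identical pairs reproduce identical draw
#' sequences, and different labels give practically independent sequences
#' (the label is hashed into the substream seed).
#'
#' @param seed integer master seed.
#' @param label short string naming the subsystem (e.g. `"wsap.grid"`).
#' @return An object of class `rng_stream` with its own private RNG state.
#' @examples
#' r1 <- rng_stream(42, "exec.rounds")
#' r2 <- rng_stream(42, "exec.rounds")
#' identical(rng_unif(r1, 5), rng_unif(r2, 5))
#' @export
rng_stream <- function(seed, label = "default") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L, nzchar(label))
  e <- new.env(parent = emptyenv())
  e$master_seed <- as.integer(seed)
  e$label <- label
  sub <- derive_stream_seed(seed, label)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(sub)
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

# Polynomial label hash folded into the master seed; kept inside the 32-bit
# signed range R requires of set.seed().
derive_stream_seed <- function(seed, label) {
  m <- 2147483629
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  as.integer((h + (as.double(seed) %% m) * 7919 + 1) %% m)
}

#' Evaluate an expression under a stream's private RNG state
#'
#' Swaps the stream's saved state into the session RNG, evaluates `expr`,
#' saves the advanced state back and restores whatever state the session had.
#'
#' @param rng an [rng_stream()].
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

#' @rdname with_rng
#' @param n number of draws.
#' @export
rng_unif <- function(rng, n = 1L) with_rng(rng, stats::runif(n))

#' @rdname with_rng
#' @param p success probability.
#' @export
rng_bern <- function(rng, p) with_rng(rng, stats::runif(1L)) < p

#' @rdname with_rng
#' @param max upper bound; draws are uniform on `1..max`.
#' @export
rng_int <- function(rng, n = 1L, max) {
  stopifnot(max >= 1)
  as.integer(floor(rng_unif(rng, n) * max)) + 1L
}

#' @rdname with_rng
#' @param x vector to sample from.
#' @param size sample size.
#' @param replace sample with replacement?
#' @export
rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  with_rng(rng, sample(x, size = size, replace = replace))
}

#' @rdname with_rng
#' @param median_ms,sigma lognormal response-time parameters.
#' @export
rng_lognormal_ms <- function(rng, n = 1L, median_ms, sigma) {
  with_rng(rng, stats::rlnorm(n, meanlog = log(median_ms), sdlog = sigma))
}
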