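#' Derive a reproducible substream seed
#'
#' One master seed fans out to named substreams (phantom, noise, init,
#' shuffle, ...) so that pipeline stages can be re-seeded independently and a
#' dataset is reproducible even if phantoms are generated out of order.
#' The map is a fixed integer hash; it has no statistical ambition beyond
#' decorrelating streams.
#'
#' @param master integer master seed
#' @param stream character stream name
#' @param index non-negative integer substream index (e.g. phantom number)
#' @return an integer seed in \code{[0, 2^31 - 2]}
#' @export
substream_seed <- function(master, stream = "default", index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, index >= 0)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  # 64-bit-safe modular arithmetic via doubles (all terms < 2^53)
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + as.numeric(index) * 69621 + h * 16807) %% m
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
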