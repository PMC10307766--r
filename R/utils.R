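# RNG stream plumbing. All stochastic entry points take an integer seed and
# manage .Random.seed explicitly, so no call mutates the caller's RNG state
# and identical seeds give identical results.

.rng_snapshot <- function() {
  get0(".Random.seed", envir = globalenv(), inherits = FALSE)
}

.rng_restore <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# A fresh RNG state initialised from `seed` (does not disturb the caller's).
.rng_state <- function(seed) {
  old <- .rng_snapshot()
  on.exit(.rng_restore(old))
  set.seed(seed)
  get(".Random.seed", envir = globalenv())
}

.rng_use <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

.rng_current <- function() get(".Random.seed", envir = globalenv())

#' Derive a reproducible child seed
#'
#' Hashes an arbitrary mix of integers and strings (run index, instance id,
#' algorithm name, ...) into a single seed below 2^31, so that every source of
#' randomness in a multi-run experiment flows deterministically from one base
#' seed. The hash is a Lehmer-style modular recurrence; it is stable across
#' platforms because all arithmetic stays below 2^53.
#'
#' @param ... integers and/or character scalars/vectors to mix.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "dga", 7L)
#' @export
derive_seed <- function(...) {
  h <- 17
  for (p in list(...)) {
    codes <- if (is.character(p)) utf8ToInt(paste(p, collapse = "\r")) else as.numeric(p)
    for (x in codes) h <- (h * 48271 + x) %% 2147483647
  }
  as.integer(h)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
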