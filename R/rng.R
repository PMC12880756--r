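# Deterministic keyed randomness.
#
# Stochastic cost families and the random heuristic draw from a stream keyed
# on (seed, family tag, vertex, time) rather than from a shared sequential
# generator.  A cost at a given (vertex, turn) is therefore a pure function of
# the seed, independent of the order in which callers evaluate costs -- which
# is what makes replaying a stored trace reproduce it exactly.

#' Mix arbitrary tags into a 31-bit seed
#'
#' Combines integers and strings into a deterministic seed in
#' `[0, 2^31 - 2]`, suitable for `set.seed()`.
#'
#' @param ... integer or character tags; order matters.
#' @return a single non-negative integer.
#' @keywords internal
hash_seed <- function(...) {
  parts <- list(...)
  h <- 17
  mix <- function(h, x) ((h * 31 + x) %% 2147483629)
  for (p in parts) {
    if (is.character(p)) {
      for (s in p) {
        for (b in utf8ToInt(s)) h <- mix(h, b)
        h <- mix(h, 3L)
      }
    } else {
      for (v in p) h <- mix(h, as.numeric(v) %% 2147483629)
      h <- mix(h, 7L)
    }
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so package-internal draws
#' never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# One uniform deviate in [0,1) keyed on the given tags.
keyed_runif <- function(...) {
  with_local_seed(hash_seed(...), stats::runif(1))
}

# One uniform integer in [lo, hi] keyed on the given tags.
keyed_rint <- function(lo, hi, ...) {
  lo + floor(keyed_runif(...) * (hi - lo + 1L))
}

# A keyed permutation of seq_len(n).
keyed_shuffle <- function(n, ...) {
  with_local_seed(hash_seed(...), sample.int(n))
}
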