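#' Derive a reproducible substream seed from a master seed and a name
#'
#' Stage- and subject-level randomness is driven by named substreams so that,
#' for example, adding subjects to a cohort never perturbs the draws of
#' subjects that were already present. The substream seed is a deterministic
#' 31-bit hash of the master seed and the stream name.
#'
#' @param master integer master seed.
#' @param key character stream name (e.g. `"subject:CD01"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; doubles are exact well past this
  h <- (abs(master) %% m)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% m
  }
  # Lehmer scramble to decorrelate nearby keys
  h <- (h * 48271) %% m
  h <- (h * 48271 + 12345) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a named RNG substream
#'
#' Saves and restores the caller's RNG state, so library code never clobbers
#' user-level random number sequences.
#'
#' @param master integer master seed.
#' @param key character stream name.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(master, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(master, key))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
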