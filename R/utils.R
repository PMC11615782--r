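#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's RNG stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-module child seed from a global seed
#'
#' All randomness in multi-stage pipelines flows from one global seed; each
#' stage gets a distinct deterministic child stream. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stream small integer stream index.
#' @return integer child seed.
#' @keywords internal
child_seed <- function(seed, stream) {
  (as.integer(seed) * 2654435L + as.integer(stream) * 97L) %% 2147483647L
}

# Fix the sign of each column of a score/loading pair so the largest-magnitude
# loading entry is positive. Makes PCA output reproducible across backends.
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
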