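#' Inverse logit
#'
#' @param x numeric vector of log-odds.
#' @return Probabilities \code{1 / (1 + exp(-x))}.
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically maps a master seed plus integer tags (e.g. replicate
#' index, training-set size) to a new seed below 2^31, so any unit of work
#' (one trait replicate, one training split) can be re-run in isolation.
#'
#' @param seed master seed (single integer).
#' @param ... integer tags identifying the work unit.
#' @return A single integer in [1, 2^31 - 1].
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  stopifnot(all(is.finite(tags)))
  m <- 2^31 - 1
  s <- 0
  # 64-bit-safe mixing in doubles: all intermediates stay below 2^53
  for (t in as.numeric(tags)) {
    s <- (s * 69069 + (t %% m) * 30269 + 104729) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs \code{expr}, and restores the caller's RNG state, so
#' seeded operations do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
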