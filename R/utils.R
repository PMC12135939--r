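#' @keywords internal
"_PACKAGE"

## Internal assertion helpers. Errors name the offending argument so that
## parameter errors from the generators satisfy the "naming the field" contract.

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (positive && x <= 0) stop_field(field, "must be strictly positive")
  if (nonneg && x < 0) stop_field(field, "must be nonnegative")
  if (integerish && x != round(x)) stop_field(field, "must be an integer")
  if (x < lower || x > upper)
    stop_field(field, sprintf("must be in [%s, %s]", lower, upper))
  invisible(x)
}

check_triple <- function(x, field, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop_field(field, "must be a numeric triple")
  if (positive && any(x <= 0)) stop_field(field, "must be strictly positive")
  if (integerish && any(x != round(x))) stop_field(field, "must be integers")
  invisible(x)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state, so the package's seeded
#' generators never perturb the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation: one user-facing seed fans out to the
## package's independent random streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483629
}
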