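#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# hours per reported month (30.42-day months)
HOURS_PER_MONTH <- 730

#' Convert simulation hours to months
#' @param hours Time in hours.
#' @return Time in 30.42-day months (730 hr).
#' @export
hours_to_months <- function(hours) hours / HOURS_PER_MONTH

stopifnot_finite <- function(x, name) {
  if (any(!is.finite(x))) stop(sprintf("non-finite values in %s", name), call. = FALSE)
}

same_shape <- function(a, b) identical(dim(a), dim(b))
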