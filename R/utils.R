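# Internal helpers: seeded RNG scoping, seed fan-out, rounding.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random number stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based fan-out: mixes the master seed with a sequence of integer
#' indices (plot, year, replicate, ...) through a multiplicative congruential
#' step so that every simulated stream is independent yet fully determined by
#' the master seed. Result is kept in `[0, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.double(idx[k]) * 16807 + k) %% 2147483647
  }
  as.integer(h)
}

# Nearest integer, halves away from zero (matches hand-rounded report tables;
# base round() goes to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
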