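# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed
#'
#' Deterministic integer stream derivation so that every generator call in a
#' cohort gets its own reproducible seed. Kept below 2^31 - 1.
#'
#' @param seed root integer seed
#' @param k stream index (non-negative integer)
#' @return an integer seed
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483629
  as.integer(((as.numeric(seed) %% m) * 48271 + as.numeric(k) * 7919) %% m) + 1L
}

# run expr with a private RNG state; global .Random.seed is untouched
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
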