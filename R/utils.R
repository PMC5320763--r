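# internal helpers shared across modules

#' @useDynLib casemap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  if (is.null(class)) stop(msg, call. = FALSE)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points route through this so a single seed argument
# gives bit-identical reruns without clobbering the session RNG.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
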