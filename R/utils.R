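#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rlnorm runif rexp rnorm rnbinom plogis qlogis optim
#'   t.test aov anova pt qt p.adjust setNames complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-unit seed derivation, kept inside 32-bit integer range.
deriveSeed <- function(master, index) {
  as.integer((as.double(master) * 7919 + as.double(index) * 104729) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertScalarNumber <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stopf("`%s` must be a single number >= %s", name, format(min))
  invisible(x)
}
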