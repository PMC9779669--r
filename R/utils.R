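#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnbinom rpois rnorm runif rexp sd cor cor.test lm predict
#'   coef quantile median approx poly setNames complete.cases step AIC
#'   wilcox.test as.formula resid
#' @importFrom utils head combn
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## Every stochastic entry point in the package routes through this, which is
## what makes generators and simulators pure functions of (arguments, seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a stream of child seeds from a master seed, each below 2^31.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

geometricMean <- function(x) exp(mean(log(x)))

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
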