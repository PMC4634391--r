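#' @importFrom stats approx convolve predict quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

## Run an expression under a temporary RNG state seeded with `seed`.
## With seed = NULL the current RNG stream is used (and advanced).
withSeed <- function(seed, expr) {
    if (is.null(seed)) {
        return(expr)
    }
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
        stop("'seed' must be a single finite number or NULL")
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            },
            add = TRUE
        )
    }
    set.seed(as.integer(seed))
    expr
}

## Derive per-unit child seeds from a master seed, each below 2^31.
childSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot2 <- function(cond, msg) {
    if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
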