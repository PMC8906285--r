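## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' perturb the caller's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed)
        oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hasSeed)
            assign(".Random.seed", oldSeed, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Linear interpolation with linear (not constant) extrapolation at both ends.
## x must be sorted ascending and distinct; used for LOWESS curve evaluation.
interpLinearExtrap <- function(x, y, xout) {
    if (length(x) == 1L)
        return(rep(y, length(xout)))
    res <- stats::approx(x, y, xout = xout, rule = 2)$y
    lo <- xout < x[1L]
    hi <- xout > x[length(x)]
    if (any(lo)) {
        s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
        res[lo] <- y[1L] + s * (xout[lo] - x[1L])
    }
    if (any(hi)) {
        n <- length(x)
        s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
        res[hi] <- y[n] + s * (xout[hi] - x[n])
    }
    res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Autodetect delimiter (tab vs comma) from the header line of a text table.
detectDelim <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}
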