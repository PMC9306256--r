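# Internal helpers.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

clip01 <- function(x) {
    x[] <- pmin(1, pmax(0, x))  # keep dim/names: pmin would drop them
    x
}

#' The standard titration mixing fractions
#'
#' The eleven known human-DNA proportions used to build mixture standard
#' curves.
#' @return Numeric vector of fractions.
#' @export
titration_fractions <- function() {
    c(0, 0.05, 0.1, 0.15, 0.25, 0.5, 0.75, 0.85, 0.9, 0.95, 1)
}
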