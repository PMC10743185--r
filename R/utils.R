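## Evaluate an expression under a temporary RNG state; the caller's
## .Random.seed is restored afterwards.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Pairwise squared Euclidean distances between the rows of X.
.rowDist2 <- function(X) {
    sq <- rowSums(X^2)
    D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    D[D < 0] <- 0
    D
}
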