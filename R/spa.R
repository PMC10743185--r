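#' Successive projections chain from one start variable
#'
#' Builds the SPA ordering: starting from `start`, every unselected
#' column is replaced by its component orthogonal to the span of the
#' selected columns, and the column with the largest residual norm is
#' appended, until `maxVars` variables are selected or every residual
#' norm falls below `tol`. Collinear candidates are annihilated by the
#' projection and never selected while independent columns remain.
#'
#' The matrix is used as given; center the columns first (with
#' calibration means) for the usual SPA behaviour, as [spaSelect()] does.
#'
#' @param X candidate matrix, samples in rows.
#' @param start starting column index.
#' @param maxVars chain length cap, `<= min(nrow(X) - 1, ncol(X))`.
#' @param tol residual-norm stopping threshold.
#' @return integer index sequence beginning with `start`, no duplicates.
#' @export
spaChain <- function(X, start, maxVars, tol = 1e-10) {
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    start <- as.integer(start)
    if (start < 1L || start > p) stop("start out of range")
    maxVars <- as.integer(min(maxVars, n - 1L, p))
    if (maxVars < 1L) stop("maxVars must be >= 1")
    R <- X
    chain <- integer(0)
    cur <- start
    repeat {
        chain <- c(chain, cur)
        if (length(chain) >= maxVars) break
        u <- R[, cur]
        nu <- sum(u^2)
        if (nu > 0)
            R <- R - u %*% (crossprod(u, R) / nu)
        norms <- sqrt(colSums(R^2))
        norms[chain] <- -Inf
        cur <- which.max(norms)
        if (norms[cur] < tol) break
    }
    chain
}

#' Successive projections algorithm variable selection
#'
#' For every candidate start variable a projection chain is built with
#' [spaChain()]; every prefix of length `minVars..maxVars` is fitted by
#' MLR on the calibration set and scored by RMSE on the validation set.
#' The global minimum wins, ties broken toward shorter prefixes and then
#' smaller start indices. The spectra passed in should already be on the
#' modelling preprocessing lineage (typically an OPS-reduced matrix).
#'
#' By default the validation pair is an external set (the Kennard-Stone
#' prediction set, matching the original prediction-error-driven subset
#' choice, which lets the prediction set influence selection);
#' `validation = "cv"` instead scores prefixes by venetian
#' cross-validated MLR on the calibration set only, for leakage-averse
#' workflows.
#'
#' @param Xcal,ycal calibration spectra and reference values.
#' @param Xval,yval validation spectra and reference values (disjoint
#'   from calibration); ignored when `validation = "cv"`.
#' @param minVars,maxVars prefix length range; `maxVars` defaults to
#'   `min(30, n/5)` and is capped at `n - 2`.
#' @param starts `"all"` (every column when p <= 2000, else the 200
#'   columns best correlated with y) or an explicit index vector.
#' @param validation `"external"` (default) or `"cv"`.
#' @param folds folds for `validation = "cv"`.
#' @return an `SPAResult` (classed list): `chains` (per evaluated start),
#'   `winningStart`, `rmseCurve` (RMSE vs prefix size for the winning
#'   start), `chosen` (winning chain prefix, selection order),
#'   `chosenSize` and `chosenRmse`.
#' @export
spaSelect <- function(Xcal, ycal, Xval = NULL, yval = NULL, minVars = 1L,
                      maxVars = NULL, starts = "all",
                      validation = c("external", "cv"), folds = 5L) {
    validation <- match.arg(validation)
    Xcal <- as.matrix(Xcal); ycal <- as.numeric(ycal)
    n <- nrow(Xcal); p <- ncol(Xcal)
    if (validation == "external") {
        if (is.null(Xval) || is.null(yval))
            stop("external validation needs Xval and yval")
        Xval <- as.matrix(Xval)
    }
    if (is.null(maxVars)) maxVars <- min(30L, floor(n / 5))
    maxVars <- as.integer(min(maxVars, n - 2L, p))
    minVars <- as.integer(minVars)
    if (minVars < 1L || minVars > maxVars)
        stop("need 1 <= minVars <= maxVars")
    if (identical(starts, "all")) {
        starts <- if (p <= 2000L) seq_len(p)
        else order(-abs(as.vector(stats::cor(Xcal, ycal))))[1:200]
    }
    starts <- as.integer(starts)
    ctr <- colMeans(Xcal)
    Xc <- sweep(Xcal, 2L, ctr, "-")
    foldid <- if (validation == "cv") .foldAssign(n, folds) else NULL
    chains <- list()
    bestRmse <- Inf; bestStart <- NA_integer_; bestLen <- NA_integer_
    curves <- list()
    for (s in starts) {
        chain <- spaChain(Xc, s, maxVars)
        chains[[as.character(s)]] <- chain
        lens <- seq.int(minVars, min(maxVars, length(chain)))
        if (!length(lens)) next
        curve <- rep(NA_real_, length(lens))
        for (i in seq_along(lens)) {
            idx <- chain[seq_len(lens[i])]
            r <- tryCatch({
                if (validation == "external") {
                    m <- fitMLR(Xcal, ycal, idx)
                    rmse(yval, predict(m, Xval))
                } else {
                    pred <- numeric(n)
                    for (k in seq_len(folds)) {
                        te <- which(foldid == k)
                        m <- fitMLR(Xcal[-te, , drop = FALSE], ycal[-te],
                                    idx)
                        pred[te] <- predict(m, Xcal[te, , drop = FALSE])
                    }
                    rmse(ycal, pred)
                }
            }, error = function(e) NA_real_)   # rank-deficient: skip
            curve[i] <- r
            better <- !is.na(r) &&
                (r < bestRmse ||
                 (r == bestRmse && (lens[i] < bestLen ||
                  (lens[i] == bestLen && s < bestStart))))
            if (better) {
                bestRmse <- r; bestStart <- s; bestLen <- lens[i]
            }
        }
        curves[[as.character(s)]] <- data.frame(size = lens, rmse = curve)
    }
    if (!is.finite(bestRmse)) stop("no SPA subset could be evaluated")
    chain <- chains[[as.character(bestStart)]]
    structure(list(chains = chains, winningStart = bestStart,
                   rmseCurve = curves[[as.character(bestStart)]],
                   chosen = chain[seq_len(bestLen)], chosenSize = bestLen,
                   chosenRmse = bestRmse, minVars = minVars,
                   maxVars = maxVars, validation = validation),
              class = "SPAResult")
}

#' @export
print.SPAResult <- function(x, ...) {
    cat(sprintf(
        "SPA selection: %d variables (start %d, %s RMSE %.4g, %d starts)\n",
        x$chosenSize, x$winningStart, x$validation, x$chosenRmse,
        length(x$chains)))
    invisible(x)
}
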