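#' Ordered predictors selection run for one informative vector
#'
#' Variables are ranked by |score| descending; the candidate subsets are
#' the ranking prefixes of sizes `window`, `window + increment`,
#' `window + 2 increment`, ... up to `p` (the full set is always
#' included as the last candidate). Each prefix is scored by venetian
#' cross-validated PLS at `hModel` latent variables (capped by the prefix
#' size and fold size); the prefix with the lowest RMSECV wins, ties
#' going to the smaller subset.
#'
#' @param X calibration spectra, samples in rows.
#' @param y calibration reference values.
#' @param vector an [informativeVector()] result (or any list with a
#'   numeric `values` field of length `ncol(X)`).
#' @param window first prefix size, >= 1.
#' @param increment prefix growth step, >= 1.
#' @param folds cross-validation folds (venetian).
#' @param hModel latent variables of the evaluation models.
#' @return a `SelectionResult` (classed list): `method`, `kind`,
#'   `ranking` (full variable ordering), `sizes`, `rmsecv`, `rcv2` per
#'   candidate, `chosenSize`, `chosen` (selected original indices, sorted)
#'   and the evaluation settings.
#' @export
opsRun <- function(X, y, vector, window, increment, folds = 5L, hModel) {
    X <- as.matrix(X); y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    vals <- abs(vector$values)
    if (length(vals) != p) stop("vector length must equal ncol(X)")
    window <- as.integer(window); increment <- as.integer(increment)
    if (window < 1L || window > p) stop("window must be in 1..p")
    if (increment < 1L) stop("increment must be >= 1")
    ranking <- order(-vals)
    sizes <- unique(c(seq.int(window, p, by = increment), p))
    foldid <- .foldAssign(n, folds)
    minTrain <- n - max(tabulate(foldid, folds))
    Xr <- X[, ranking, drop = FALSE]
    K <- matrix(0, n, n)
    prev <- 0L
    rmsecv <- numeric(length(sizes)); rcv2 <- numeric(length(sizes))
    for (i in seq_along(sizes)) {
        sz <- sizes[i]
        add <- Xr[, (prev + 1L):sz, drop = FALSE]
        K <- K + tcrossprod(add)
        prev <- sz
        nLv <- min(hModel, sz, minTrain - 1L)
        sc <- .gramCVScore(K, y, foldid, nLv)
        rmsecv[i] <- sc["rmsecv"]; rcv2[i] <- sc["rcv2"]
    }
    best <- which.min(rmsecv)    # first minimum = smallest size on ties
    chosen <- sort(ranking[seq_len(sizes[best])])
    structure(list(method = "OPS", kind = vector$kind, ranking = ranking,
                   sizes = sizes, rmsecv = rmsecv, rcv2 = rcv2,
                   chosenSize = sizes[best], chosen = chosen,
                   chosenRmsecv = rmsecv[best], chosenRcv2 = rcv2[best],
                   window = window, increment = increment,
                   hModel = hModel, folds = folds),
              class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
    cat(sprintf("%s selection: %d of %d variables (vector %s, RMSECV %.4g)\n",
                x$method, length(x$chosen), length(x$ranking),
                x$kind %||% "-", x$chosenRmsecv))
    invisible(x)
}

.opsDefaults <- function(n, p, hVec, hModel, window, increment, maxPilotLv,
                         X, y, folds) {
    if (is.null(hVec) || is.null(hModel)) {
        maxLv <- min(maxPilotLv, p,
                     n - ceiling(n / folds) - 1L)
        cv <- crossValidatePLS(X, y, maxLv = max(1L, maxLv), folds = folds)
        if (is.null(hVec)) hVec <- cv$chosen
        if (is.null(hModel)) hModel <- cv$chosen
    }
    if (is.null(window)) window <- max(1L, min(10L * hVec, p))
    if (is.null(increment)) increment <- max(1L, round(p / 50))
    list(hVec = as.integer(hVec), hModel = as.integer(hModel),
         window = as.integer(window), increment = as.integer(increment))
}

#' Automated ordered predictors selection (autoOPS)
#'
#' Computes all eight informative-vector kinds (REG, COR, SQR, VIP, NAS,
#' COV, URXY, WGHT) plus the pairwise products of min-max-normalized
#' vectors, runs an [opsRun()] for every vector (and every window /
#' increment combination when vectors are supplied), and returns the
#' globally best selection: lowest RMSECV, ties broken toward fewer
#' variables and then lexicographic vector-kind name.
#'
#' When `hVec`/`hModel` are not given, both default to the
#' latent-variable count chosen by full-spectrum cross-validation (the
#' pilot model); `window` defaults to `10 * hVec` and `increment` to
#' `p / 50` (at least 1).
#'
#' @inheritParams opsRun
#' @param hVec latent variables for the informative vectors.
#' @param hModel latent variables for the evaluation models.
#' @param window,increment prefix schedule; vectors define a grid.
#' @param combinations include pairwise product vectors (default TRUE).
#' @param maxPilotLv cap for the pilot cross-validation.
#' @return the winning `SelectionResult` (method `"autoOPS"`), with a
#'   `summary` data frame of every run's winning subset.
#' @export
autoOPS <- function(X, y, hVec = NULL, hModel = NULL, window = NULL,
                    increment = NULL, folds = 5L, combinations = TRUE,
                    maxPilotLv = 15L) {
    X <- as.matrix(X); y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    def <- .opsDefaults(n, p, hVec, hModel, window, increment, maxPilotLv,
                        X, y, folds)
    vecs <- .allInformativeVectors(X, y, def$hVec,
                                   combinations = combinations)
    grid <- expand.grid(window = def$window, increment = def$increment)
    runs <- list()
    for (v in vecs) {
        for (g in seq_len(nrow(grid))) {
            r <- opsRun(X, y, v, grid$window[g], grid$increment[g],
                        folds = folds, hModel = def$hModel)
            runs[[length(runs) + 1L]] <- r
        }
    }
    if (!length(runs)) stop("no OPS runs could be evaluated")
    summary <- data.frame(
        kind = vapply(runs, `[[`, character(1), "kind"),
        window = vapply(runs, `[[`, integer(1), "window"),
        increment = vapply(runs, `[[`, integer(1), "increment"),
        nVars = vapply(runs, `[[`, integer(1), "chosenSize"),
        rmsecv = vapply(runs, `[[`, numeric(1), "chosenRmsecv"))
    best <- order(summary$rmsecv, summary$nVars, summary$kind)[1L]
    out <- runs[[best]]
    out$method <- "autoOPS"
    out$summary <- summary
    out$hVec <- def$hVec
    out
}

#' Feedback ordered predictors selection (feedOPS)
#'
#' Iterates [autoOPS()]: each round restricts the matrix to the previous
#' round's selected variables and reselects. Rounds continue while the
#' RMSECV improves by at least `relTol` (relative) and the subset keeps
#' changing, up to `maxRounds`; a round that worsens the RMSECV is
#' rejected and iteration stops with the incumbent, so the final RMSECV
#' never exceeds round 1's.
#'
#' @inheritParams autoOPS
#' @param maxRounds maximum selection rounds.
#' @param relTol relative RMSECV improvement below which iteration stops.
#' @return the final `SelectionResult` (method `"feedOPS"`, indices in
#'   original coordinates) with a `rounds` data frame trace.
#' @export
feedOPS <- function(X, y, hVec = NULL, hModel = NULL, window = NULL,
                    increment = NULL, folds = 5L, combinations = TRUE,
                    maxRounds = 10L, relTol = 1e-3) {
    X <- as.matrix(X)
    cur <- seq_len(ncol(X))
    best <- NULL
    trace <- data.frame(round = integer(), kind = character(),
                        nVars = integer(), rmsecv = numeric())
    for (r in seq_len(maxRounds)) {
        res <- autoOPS(X[, cur, drop = FALSE], y, hVec = hVec,
                       hModel = hModel, window = window,
                       increment = increment, folds = folds,
                       combinations = combinations)
        res$chosen <- cur[res$chosen]
        res$ranking <- cur[res$ranking]
        trace <- rbind(trace, data.frame(
            round = r, kind = res$kind, nVars = res$chosenSize,
            rmsecv = res$chosenRmsecv))
        if (!is.null(best)) {
            if (res$chosenRmsecv > best$chosenRmsecv) break
            improved <- (best$chosenRmsecv - res$chosenRmsecv) >
                relTol * best$chosenRmsecv
            unchanged <- identical(res$chosen, best$chosen)
            best <- res
            if (!improved || unchanged) break
        } else best <- res
        cur <- best$chosen
        if (length(cur) < 2L) break
    }
    best$method <- "feedOPS"
    best$rounds <- trace
    best
}

#' Interval ordered predictors selection (iOPS)
#'
#' The spectrum is partitioned into contiguous intervals of
#' `intervalSize` variables (the last interval may be shorter);
#' [autoOPS()] runs inside each interval (its window capped by the
#' interval width, so an interval narrower than the window is evaluated
#' as a single candidate), the per-interval selections are concatenated
#' into a reduced matrix, and a final [autoOPS()] over the reduced matrix
#' produces the result in original-index space.
#'
#' @inheritParams autoOPS
#' @param intervalSize variables per interval; default `ceiling(p / 10)`.
#' @return a `SelectionResult` (method `"iOPS"`) with an `intervals`
#'   list recording each interval's range and selection.
#' @export
iOPS <- function(X, y, intervalSize = NULL, hVec = NULL, hModel = NULL,
                 window = NULL, increment = NULL, folds = 5L,
                 combinations = TRUE) {
    X <- as.matrix(X)
    p <- ncol(X)
    if (is.null(intervalSize)) intervalSize <- ceiling(p / 10)
    intervalSize <- as.integer(intervalSize)
    if (intervalSize < 1L) stop("intervalSize must be >= 1")
    starts <- seq.int(1L, p, by = intervalSize)
    intervals <- list()
    pooled <- integer(0)
    for (s in starts) {
        cols <- s:min(s + intervalSize - 1L, p)
        wInt <- if (is.null(window)) NULL else min(window, length(cols))
        res <- autoOPS(X[, cols, drop = FALSE], y, hVec = hVec,
                       hModel = hModel, window = wInt,
                       increment = increment, folds = folds,
                       combinations = combinations)
        sel <- cols[res$chosen]
        pooled <- c(pooled, sel)
        intervals[[length(intervals) + 1L]] <-
            list(columns = range(cols), selected = sel,
                 rmsecv = res$chosenRmsecv, kind = res$kind)
    }
    pooled <- sort(unique(pooled))
    wFin <- if (is.null(window)) NULL else min(window, length(pooled))
    final <- autoOPS(X[, pooled, drop = FALSE], y, hVec = hVec,
                     hModel = hModel, window = wFin,
                     increment = increment, folds = folds,
                     combinations = combinations)
    final$chosen <- pooled[final$chosen]
    final$ranking <- pooled[final$ranking]
    final$method <- "iOPS"
    final$intervals <- intervals
    final$intervalSize <- intervalSize
    final
}
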