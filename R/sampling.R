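#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min-distance selection on Euclidean distances
#' between (preprocessed) spectra: the pair at maximal distance seeds the
#' calibration set, then the sample whose minimum distance to the
#' selected set is largest is added until `round(ratio * n)` samples are
#' selected. Ties are broken toward the lowest index. The remainder forms
#' the prediction set.
#'
#' @param X numeric matrix, samples in rows (use the spectra actually
#'   entering the model, i.e. after preprocessing).
#' @param ratio target calibration fraction in (0, 1); the split must
#'   leave at least one prediction sample and select at least two.
#' @return a `SplitResult` (classed list) with `calibration`,
#'   `prediction` (index vectors partitioning `1..n`) and `ratio`.
#' @export
kennardStone <- function(X, ratio = 0.75) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 2L) stop("need at least 2 samples")
    if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
    nCal <- round(ratio * n)
    if (nCal >= n) stop("split leaves no prediction samples")
    if (nCal < 2L) stop("split selects fewer than 2 calibration samples")
    D <- .rowDist2(X)
    ## seed pair: maximal distance, first (i < j) scan order on ties
    up <- which(upper.tri(D), arr.ind = TRUE)
    best <- up[which.max(D[upper.tri(D)]), ]
    sel <- c(best[1L], best[2L])
    minD <- pmin(D[, sel[1L]], D[, sel[2L]])
    while (length(sel) < nCal) {
        minD[sel] <- -Inf
        nxt <- which.max(minD)    # which.max takes the first on ties
        sel <- c(sel, nxt)
        minD <- pmin(minD, D[, nxt])
    }
    sel <- as.integer(sel)
    structure(list(calibration = sel,
                   prediction = setdiff(seq_len(n), sel),
                   ratio = ratio),
              class = "SplitResult")
}

#' @export
print.SplitResult <- function(x, ...) {
    cat(sprintf("Kennard-Stone split: %d calibration / %d prediction (ratio %.2f)\n",
                length(x$calibration), length(x$prediction), x$ratio))
    invisible(x)
}

#' Monte Carlo prediction-error outlier scan
#'
#' Repeatedly splits the samples at random into a training part and a
#' test part, fits a PLS model on the training part (mean-centered
#' internally) and records the signed prediction error (yhat - y) of
#' every test sample. After all iterations each sample's errors are
#' summarized by their MEAN and sample SD: samples that are hard to
#' predict whenever they are held out stand out on the MEAN/SD diagnostic
#' map. The default iteration count targets about 500 test-set
#' appearances per sample.
#'
#' @param X numeric matrix, samples in rows.
#' @param y reference values.
#' @param nLv latent variables of the scanning PLS model.
#' @param iterations Monte Carlo iterations; default
#'   `ceiling(500 / (1 - trainFraction))`.
#' @param trainFraction fraction of samples in each training part.
#' @param seed integer seed; a seeded scan is bit-reproducible.
#' @return an `OutlierDiagnostics` (classed list) with per-sample `mean`,
#'   `sd`, `count` (test appearances; samples never tested get `NA`
#'   summaries and a warning), `flagged` (empty until [flagOutliers()]),
#'   and the scan settings.
#' @export
monteCarloOutliers <- function(X, y, nLv, iterations = NULL,
                               trainFraction = 0.75, seed = 1L) {
    X <- as.matrix(X); y <- as.numeric(y)
    n <- nrow(X)
    if (length(y) != n) stop("length(y) must equal nrow(X)")
    if (trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must be in (0, 1)")
    if (is.null(iterations))
        iterations <- as.integer(ceiling(500 / (1 - trainFraction)))
    iterations <- as.integer(iterations)
    if (iterations < 1L) stop("iterations must be >= 1")
    nTrain <- max(2L, round(trainFraction * n))
    if (nTrain >= n) stop("trainFraction leaves no test samples")
    nLv <- as.integer(min(nLv, nTrain - 1L, ncol(X)))
    K <- tcrossprod(X)
    sums <- numeric(n); sums2 <- numeric(n); count <- integer(n)
    withSeed(seed, {
        for (it in seq_len(iterations)) {
            tr <- sample.int(n, nTrain)
            te <- setdiff(seq_len(n), tr)
            pred <- .kernelPLSPredict(K[tr, tr, drop = FALSE],
                                      K[te, tr, drop = FALSE],
                                      y[tr], nLv)[, nLv]
            e <- pred - y[te]
            sums[te] <- sums[te] + e
            sums2[te] <- sums2[te] + e^2
            count[te] <- count[te] + 1L
        }
    })
    mu <- ifelse(count > 0L, sums / count, NA_real_)
    sd <- ifelse(count > 1L,
                 sqrt(pmax(0, (sums2 - count * mu^2) / (count - 1L))),
                 NA_real_)
    if (any(count == 0L))
        warning(sum(count == 0L),
                " sample(s) never appeared in a test set")
    structure(list(mean = mu, sd = sd, count = count,
                   flagged = integer(0), thresholds = NULL,
                   iterations = iterations, trainFraction = trainFraction,
                   nLv = nLv, seed = seed),
              class = "OutlierDiagnostics")
}

#' Flag outliers on the MEAN/SD diagnostic map
#'
#' Applies a robust automatic rule to [monteCarloOutliers()] diagnostics:
#' a sample is flagged when `|MEAN| > median(|MEAN|) + k * MAD(|MEAN|)`
#' or `SD > median(SD) + k * MAD(SD)` (MAD with the usual 1.4826 normal
#' consistency factor). This replaces visual inspection of the map with a
#' reproducible threshold.
#'
#' @param d an `OutlierDiagnostics`.
#' @param k threshold multiplier (default 3).
#' @param tol absolute floor below which diagnostics are treated as
#'   numerically zero (an exactly fitting model never yields flags).
#' @return `d` with `flagged` and `thresholds` filled in.
#' @export
flagOutliers <- function(d, k = 3, tol = sqrt(.Machine$double.eps)) {
    stopifnot(inherits(d, "OutlierDiagnostics"))
    am <- abs(d$mean)
    thrM <- max(stats::median(am, na.rm = TRUE) +
                k * stats::mad(am, na.rm = TRUE), tol)
    thrS <- max(stats::median(d$sd, na.rm = TRUE) +
                k * stats::mad(d$sd, na.rm = TRUE), tol)
    d$flagged <- which((!is.na(am) & am > thrM) |
                       (!is.na(d$sd) & d$sd > thrS))
    d$thresholds <- c(mean = thrM, sd = thrS, k = k)
    d
}

#' @export
print.OutlierDiagnostics <- function(x, ...) {
    cat(sprintf(
        "Monte Carlo outlier scan: %d iterations, train fraction %.2f, %d LV\n",
        x$iterations, x$trainFraction, x$nLv))
    if (length(x$flagged)) {
        cat("flagged samples:", paste(x$flagged, collapse = ", "), "\n")
    } else cat("no samples flagged (run flagOutliers)\n")
    invisible(x)
}
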