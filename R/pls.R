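#' @include AllClasses.R AllGenerics.R
NULL

#' Fit a univariate PLS model by NIPALS
#'
#' PLS1 with internal centering of X and y. Per component a:
#' w = X'y / ||X'y||, t = X w, p = X't / (t't), q = t'y / (t't), then X
#' and y are deflated by the extracted component. The regression vector
#' in the (centered) predictor space is b = W (P'W)^-1 q, and predictions
#' are yhat = yMean + (x - xMeans)' b.
#'
#' Extraction stops early with a warning when no covariance between X and
#' y remains (||X'y|| numerically zero).
#'
#' @param X numeric matrix, samples in rows.
#' @param y numeric response, one value per row of `X`.
#' @param nLv number of latent variables to extract,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return a [PLSModel-class].
#' @examples
#' X <- matrix(rnorm(80), 10)
#' m <- fitPLS(X, rnorm(10), nLv = 3)
#' predict(m, X)
#' @export
fitPLS <- function(X, y, nLv) {
    X <- as.matrix(X); y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    if (length(y) != n) stop("length(y) must equal nrow(X)")
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("X and y must be finite")
    nLv <- as.integer(nLv)
    if (nLv < 1L || nLv > min(n - 1L, p))
        stop("nLv must be in 1..min(n-1, p)")
    xMeans <- colMeans(X)
    yMean <- mean(y)
    E <- sweep(X, 2L, xMeans, "-")
    f <- y - yMean
    tol <- 1e-12 * max(1, sqrt(sum(f^2)) * sqrt(sum(E^2)))
    W <- matrix(0, p, nLv); P <- matrix(0, p, nLv)
    Tm <- matrix(0, n, nLv); q <- numeric(nLv)
    a <- 0L
    for (h in seq_len(nLv)) {
        w <- crossprod(E, f)
        nw <- sqrt(sum(w^2))
        if (nw <= tol) {
            warning("no remaining X-y covariance; stopped at ", a,
                    " latent variable(s)")
            break
        }
        w <- w / nw
        tv <- as.vector(E %*% w)
        tt <- sum(tv^2)
        pv <- crossprod(E, tv) / tt
        qa <- sum(tv * f) / tt
        E <- E - tcrossprod(tv, pv)
        f <- f - tv * qa
        a <- h
        W[, a] <- w; P[, a] <- pv; Tm[, a] <- tv; q[a] <- qa
    }
    if (a == 0L) {
        W <- matrix(0, p, 0); P <- matrix(0, p, 0)
        Tm <- matrix(0, n, 0); q <- numeric(0)
        b <- numeric(p)
    } else {
        W <- W[, seq_len(a), drop = FALSE]
        P <- P[, seq_len(a), drop = FALSE]
        Tm <- Tm[, seq_len(a), drop = FALSE]
        q <- q[seq_len(a)]
        b <- as.vector(W %*% solve(crossprod(P, W), q))
    }
    fitted <- yMean + as.vector(sweep(X, 2L, xMeans, "-") %*% b)
    new("PLSModel", nLv = a, W = W, scores = Tm, P = P, q = q, b = b,
        xMeans = xMeans, yMean = yMean, rmsec = rmse(y, fitted))
}

#' @describeIn fitPLS predictions for new spectra (matrix or vector).
#' @param object a fitted `PLSModel`.
#' @param newdata matrix with the model's variable count, samples in rows.
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
    X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
         else as.matrix(newdata)
    if (ncol(X) != length(object@b))
        stop("newdata has ", ncol(X), " variables; model expects ",
             length(object@b))
    as.vector(object@yMean + sweep(X, 2L, object@xMeans, "-") %*% object@b)
})

setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel: %d latent variable(s), %d variables, RMSEC %.4g\n",
                object@nLv, length(object@b), object@rmsec))
    invisible(NULL)
})

#' @describeIn fitPLS the regression vector in preprocessed X space.
#' @export
setMethod("regressionVector", "PLSModel", function(object) object@b)

#' @describeIn fitPLS number of latent variables extracted.
#' @export
setMethod("nLatent", "PLSModel", function(object) object@nLv)

## Per-LV cumulative predictions for new data from a fitted PLSModel:
## column a holds the prediction using latent variables 1..a.
.plsPredictPerLV <- function(model, X) {
    X <- as.matrix(X)
    n <- nrow(X); h <- model@nLv
    E <- sweep(X, 2L, model@xMeans, "-")
    out <- matrix(model@yMean, n, max(h, 1L))
    acc <- rep(model@yMean, n)
    for (a in seq_len(h)) {
        tv <- as.vector(E %*% model@W[, a])
        acc <- acc + tv * model@q[a]
        E <- E - tcrossprod(tv, model@P[, a])
        out[, a] <- acc
    }
    out
}

.foldAssign <- function(n, folds, scheme = c("venetian", "random"),
                        seed = NULL) {
    scheme <- match.arg(scheme)
    if (folds < 2L || folds > n) stop("folds must be in 2..n")
    id <- rep_len(seq_len(folds), n)
    if (scheme == "random") {
        if (!is.null(seed)) {
            id <- withSeed(seed, sample(id))
        } else id <- sample(id)
    }
    id
}

#' Cross-validate PLS over latent-variable counts
#'
#' For each latent-variable count 1..`maxLv`, held-out predictions are
#' accumulated over the folds (centering statistics re-fit inside each
#' training fold, as [fitPLS()] always centers internally) and RMSECV and
#' Rcv2 computed. The chosen complexity is the smallest count whose
#' RMSECV lies within `parsimony` (default 2%) of the global minimum.
#'
#' @inheritParams fitPLS
#' @param maxLv largest latent-variable count to evaluate.
#' @param folds number of folds (default 10).
#' @param scheme `"venetian"` (deterministic interleaved folds, the
#'   default) or `"random"`.
#' @param seed integer seed for the random scheme.
#' @param parsimony relative band above the minimum RMSECV within which
#'   the smallest model is preferred.
#' @return a `PLSCV` (classed list) with per-LV `rmsecv` and `rcv2`,
#'   `chosen`, `folds`, `scheme` and the fold assignment `foldid`.
#' @export
crossValidatePLS <- function(X, y, maxLv, folds = 10L,
                             scheme = c("venetian", "random"), seed = NULL,
                             parsimony = 0.02) {
    scheme <- match.arg(scheme)
    X <- as.matrix(X); y <- as.numeric(y)
    n <- nrow(X)
    foldid <- .foldAssign(n, folds, scheme, seed)
    minTrain <- n - max(tabulate(foldid, folds))
    if (minTrain < 2L) stop("a training fold has fewer than 2 samples")
    maxLv <- as.integer(maxLv)
    if (maxLv < 1L || maxLv > min(minTrain - 1L, ncol(X)))
        stop("maxLv must be in 1..min(smallest training fold - 1, p)")
    pred <- matrix(NA_real_, n, maxLv)
    for (k in seq_len(folds)) {
        te <- which(foldid == k)
        m <- fitPLS(X[-te, , drop = FALSE], y[-te], maxLv)
        pk <- .plsPredictPerLV(m, X[te, , drop = FALSE])
        if (m@nLv < maxLv)   # early stop: pad with the last usable model
            pk <- cbind(pk, matrix(pk[, max(m@nLv, 1L)], length(te),
                                   maxLv - max(m@nLv, 1L)))
        pred[te, ] <- pk[, seq_len(maxLv), drop = FALSE]
    }
    rmsecv <- apply(pred, 2L, function(p) rmse(y, p))
    rcv2 <- apply(pred, 2L, function(p) rSquared(y, p))
    chosen <- min(which(rmsecv <= min(rmsecv) * (1 + parsimony)))
    structure(list(rmsecv = rmsecv, rcv2 = rcv2, chosen = chosen,
                   folds = folds, scheme = scheme, foldid = foldid),
              class = "PLSCV")
}

#' @export
print.PLSCV <- function(x, ...) {
    cat(sprintf("PLS cross-validation (%d %s folds)\n", x$folds, x$scheme))
    tab <- data.frame(LV = seq_along(x$rmsecv), RMSECV = x$rmsecv,
                      Rcv2 = x$rcv2)
    print(tab, row.names = FALSE, digits = 4)
    cat("chosen:", x$chosen, "LV\n")
    invisible(x)
}

#' Fit a multiple linear regression on selected variables
#'
#' Ordinary least squares with intercept on the columns named by
#' `variableIndices`. Requires more samples than coefficients and a
#' full-rank selection; a rank-deficient selection is an error naming the
#' collinear columns.
#'
#' @inheritParams fitPLS
#' @param variableIndices columns of `X` to include.
#' @return an [MLRModel-class].
#' @export
fitMLR <- function(X, y, variableIndices) {
    X <- as.matrix(X); y <- as.numeric(y)
    idx <- as.integer(variableIndices)
    if (anyDuplicated(idx)) stop("duplicate variable indices")
    if (any(idx < 1L | idx > ncol(X))) stop("variable index out of range")
    if (nrow(X) <= length(idx) + 1L)
        stop("need n > number of variables + 1")
    A <- cbind(`(Intercept)` = 1, X[, idx, drop = FALSE])
    fit <- stats::lm.fit(A, y)
    if (fit$rank < ncol(A)) {
        drop <- idx[fit$qr$pivot[(fit$rank + 1L):ncol(A)] - 1L]
        stop("collinear selected column(s): ", paste(drop, collapse = ", "))
    }
    cf <- fit$coefficients
    new("MLRModel", variableIndices = idx,
        coefficients = unname(cf[-1L]), intercept = unname(cf[1L]))
}

#' @describeIn fitMLR predictions; only the stored columns are read, and
#'   `newdata` may be the full-width matrix or just the selected columns.
#' @param object a fitted `MLRModel`.
#' @param newdata matrix of spectra, samples in rows.
#' @export
setMethod("predict", "MLRModel", function(object, newdata) {
    X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
         else as.matrix(newdata)
    k <- length(object@variableIndices)
    Xs <- if (ncol(X) == k) X
          else if (ncol(X) >= max(object@variableIndices))
              X[, object@variableIndices, drop = FALSE]
          else stop("newdata is narrower than the model's variable indices")
    as.vector(object@intercept + Xs %*% object@coefficients)
})

setMethod("show", "MLRModel", function(object) {
    cat(sprintf("MLRModel: %d variable(s), intercept %.4g\n",
                length(object@variableIndices), object@intercept))
    invisible(NULL)
})
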