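## Gram-matrix (kernel) form of NIPALS PLS1. Mathematically identical to
## fitPLS + predict (asserted in the test suite) but O(n^2 h) per fit,
## independent of the variable count: with K = X X' precomputed once,
## column subsets that only ever grow (OPS prefixes) or row subsets
## (Monte Carlo resampling, CV folds) are evaluated by slicing K instead
## of refactoring X. Used by opsRun() and monteCarloOutliers().

## Cumulative per-LV test predictions from raw (uncentered) Gram blocks.
## K: ntrain x ntrain = Xtr Xtr'; Ktest: ntest x ntrain = Xte Xtr'.
.kernelPLSPredict <- function(K, Ktest, y, nLv) {
    n <- nrow(K)
    ntest <- nrow(Ktest)
    m <- rowMeans(K)
    mu <- mean(K)
    Kc <- K - outer(m, rep(1, n)) - outer(rep(1, n), m) + mu
    Ktc <- Ktest - outer(rowMeans(Ktest), rep(1, n)) -
        outer(rep(1, ntest), m) + mu
    ymean <- mean(y)
    yc <- y - ymean
    tol <- 1e-12 * max(1, sum(diag(Kc)) * sqrt(sum(yc^2)))
    out <- matrix(ymean, ntest, nLv)
    acc <- rep(ymean, ntest)
    for (a in seq_len(nLv)) {
        v <- as.vector(Kc %*% yc)            # = Xc (Xc' yc)
        s2 <- sum(yc * v)                    # = ||Xc' yc||^2
        if (s2 <= tol) { out[, a:nLv] <- acc; break }
        s <- sqrt(s2)
        tv <- v / s
        tt <- sum(tv^2)
        tte <- as.vector(Ktc %*% yc) / s     # test scores
        qa <- sum(tv * yc) / tt
        acc <- acc + tte * qa
        out[, a] <- acc
        if (a == nLv) break
        u <- tv / tt
        g <- as.vector(Kc %*% u)
        cc <- sum(u * g)
        ## symmetric rank-2 downdate: Kc - g t' - t g' + cc t t'
        gh <- g - (cc / 2) * tv
        Kc <- Kc - tcrossprod(gh, tv) - tcrossprod(tv, gh)
        Ktc <- Ktc - tcrossprod(as.vector(Ktc %*% u) - cc * tte, tv) -
            tcrossprod(tte, g)
        yc <- yc - tv * qa
        out[, (a + 1L):nLv] <- acc
    }
    out
}

## Cross-validated predictions from a full raw Gram matrix. Returns an
## n x nLv matrix of held-out cumulative predictions.
.gramCVPredict <- function(K, y, foldid, nLv) {
    n <- nrow(K)
    pred <- matrix(NA_real_, n, nLv)
    for (k in seq_len(max(foldid))) {
        te <- which(foldid == k)
        tr <- which(foldid != k)
        pred[te, ] <- .kernelPLSPredict(K[tr, tr, drop = FALSE],
                                        K[te, tr, drop = FALSE],
                                        y[tr], nLv)
    }
    pred
}

## RMSECV / Rcv2 at a fixed latent-variable count from a raw Gram matrix.
.gramCVScore <- function(K, y, foldid, nLv) {
    pred <- .gramCVPredict(K, y, foldid, nLv)
    p <- pred[, nLv]
    c(rmsecv = rmse(y, p), rcv2 = rSquared(y, p))
}
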