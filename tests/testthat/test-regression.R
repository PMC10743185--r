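test_that("PLS recovers an exact rank-1 factor with one component", {
    set.seed(21)
    t <- rnorm(12)
    p <- rnorm(6)
    X <- tcrossprod(t, p)
    y <- 2 * t + 1
    m <- fitPLS(X, y, 1)
    expect_equal(m@rmsec, 0, tolerance = 1e-10)
    expect_equal(predict(m, X), y, tolerance = 1e-8)
})

test_that("PLS stops early when y is orthogonal to the columns", {
    X <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
    y <- c(1, 1, 1, 1)            # centered y is zero: no covariance
    expect_warning(m <- fitPLS(X, y, 2), "no remaining")
    expect_equal(m@b, c(0, 0))
    expect_equal(predict(m, X), rep(1, 4))
})

test_that("PLS with all latent variables equals ordinary least squares", {
    set.seed(22)
    X <- matrix(rnorm(24), 8, 3)
    y <- rnorm(8)
    m <- fitPLS(X, y, 3)
    ols <- lm(y ~ X)
    bOls <- coef(ols)[-1]
    expect_equal(m@b, unname(bOls), tolerance = 1e-6)
    expect_equal(predict(m, X), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("PLS model structure satisfies its invariants", {
    set.seed(23)
    X <- matrix(rnorm(200), 20)
    y <- rnorm(20)
    m <- fitPLS(X, y, 5)
    expect_equal(unname(sqrt(colSums(m@W^2))), rep(1, 5), tolerance = 1e-8)
    G <- crossprod(m@scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
    ## predictions via b equal the score-recursion predictions
    Xn <- matrix(rnorm(50), 5)
    perLV <- opsnir:::.plsPredictPerLV(m, Xn)
    expect_equal(predict(m, Xn), perLV[, 5], tolerance = 1e-8)
    ## RMSEC is non-increasing in the number of latent variables
    rmsecs <- vapply(1:5, function(h) fitPLS(X, y, h)@rmsec, numeric(1))
    expect_true(all(diff(rmsecs) <= 1e-12))
    expect_error(fitPLS(X, y, 25), "nLv")
})

test_that("kernel-Gram PLS path equals the NIPALS path", {
    set.seed(24)
    X <- matrix(rnorm(15 * 40), 15)
    y <- rnorm(15)
    Xt <- matrix(rnorm(6 * 40), 6)
    m <- fitPLS(X, y, 4)
    pk <- opsnir:::.kernelPLSPredict(tcrossprod(X), tcrossprod(Xt, X), y, 4)
    expect_equal(pk, opsnir:::.plsPredictPerLV(m, Xt), tolerance = 1e-8)
})

test_that("cross-validation matches a naive per-fold refit oracle", {
    set.seed(25)
    X <- matrix(rnorm(30 * 8), 30)
    y <- rnorm(30)
    cv <- crossValidatePLS(X, y, maxLv = 3, folds = 5)
    ## naive oracle: refit fitPLS per fold per LV count
    foldid <- rep_len(1:5, 30)
    for (h in 1:3) {
        pred <- numeric(30)
        for (k in 1:5) {
            te <- which(foldid == k)
            mk <- fitPLS(X[-te, ], y[-te], h)
            pred[te] <- predict(mk, X[te, ])
        }
        expect_equal(cv$rmsecv[h], rmse(y, pred), tolerance = 1e-10)
    }
    expect_true(cv$chosen %in% 1:3)
    expect_true(all(cv$rmsecv >= 0))
})

test_that("noiseless two-factor data is explained by two latent variables", {
    set.seed(26)
    T2 <- matrix(rnorm(80), 40, 2)
    P2 <- matrix(rnorm(12), 6, 2)
    X <- tcrossprod(T2, P2)
    y <- as.vector(T2 %*% c(1, -2))
    cv <- suppressWarnings(         # exact rank-2 data stops early
        crossValidatePLS(X, y, maxLv = 5, folds = 10))
    expect_lt(cv$rmsecv[2], 1e-6 * sd(y))
    expect_lte(cv$chosen, 3)
})

test_that("leave-one-out equals n folds and venetian folds interleave", {
    set.seed(27)
    X <- matrix(rnorm(25), 5)
    y <- rnorm(5)
    cv <- crossValidatePLS(X, y, maxLv = 2, folds = 5)
    expect_identical(cv$foldid, rep_len(1:5, 5))
    ## each fold holds exactly one sample: identical to explicit LOO
    pred <- vapply(1:5, function(i)
        predict(fitPLS(X[-i, ], y[-i], 2), X[i, , drop = FALSE]),
        numeric(1))
    expect_equal(cv$rmsecv[2], rmse(y, pred), tolerance = 1e-10)
})

test_that("MLR matches the normal equations and flags collinearity", {
    ## exact affine recovery
    X <- matrix(rnorm(60), 20)
    y <- 3 * X[, 2] + 1
    m <- fitMLR(X, y, 2L)
    expect_equal(m@coefficients, 3, tolerance = 1e-10)
    expect_equal(m@intercept, 1, tolerance = 1e-10)
    ## 17 selected columns match lm on synthetic data
    set.seed(28)
    X2 <- matrix(rnorm(60 * 25), 60)
    y2 <- rnorm(60)
    idx <- sort(sample(25, 17))
    m2 <- fitMLR(X2, y2, idx)
    ref <- lm(y2 ~ X2[, idx])
    expect_equal(m2@coefficients, unname(coef(ref))[-1], tolerance = 1e-8)
    expect_equal(m2@intercept, unname(coef(ref))[1], tolerance = 1e-8)
    ## prediction reads only the stored columns
    expect_equal(predict(m2, X2), unname(fitted(ref)), tolerance = 1e-8)
    expect_equal(predict(m2, X2[, idx]), unname(fitted(ref)),
                 tolerance = 1e-8)
    ## collinear selection errors, naming the offending column
    X3 <- cbind(X[, 1], X[, 1] * 2, X[, 3])
    expect_error(fitMLR(X3, y, 1:2), "collinear")
    expect_error(fitMLR(X, y, c(1, 1)), "duplicate")
    expect_error(fitMLR(X[1:3, ], y[1:3], 1:2), "n >")
})
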