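test_that("meanCenter hits its target and replays stored means", {
    expect_equal(meanCenter(matrix(c(5, 5, 5)))$X[, 1], rep(0, 3))
    X <- matrix(rnorm(32), 8)
    r <- meanCenter(X)
    expect_equal(unname(colMeans(r$X)), rep(0, 4), tolerance = 1e-10)
    expect_equal(r$X, sweep(X, 2, colMeans(X)))       # direct oracle
    expect_equal(meanCenter(r$X)$X, r$X)              # idempotent
    ## prediction-set transform uses the supplied means
    Xnew <- matrix(rnorm(8), 2)
    expect_equal(meanCenter(Xnew, r$center)$X,
                 sweep(Xnew, 2, colMeans(X)))
    expect_error(meanCenter(Xnew, 1:3), "length")
})

test_that("autoscale standardizes with the n-1 denominator", {
    expect_equal(autoscale(matrix(1:3))$X[, 1], c(-1, 0, 1))
    set.seed(4)
    X <- matrix(rnorm(60), 10)
    r <- autoscale(X)
    oracle <- apply(X, 2, function(x) (x - mean(x)) / sd(x))
    expect_equal(r$X, oracle)
    expect_equal(unname(apply(r$X, 2, sd)), rep(1, 6), tolerance = 1e-10)
    ## replaying stored stats reproduces the fit
    expect_equal(autoscale(X, r$center, r$scale)$X, r$X)
    Xz <- X; Xz[, 3] <- 2
    expect_error(autoscale(Xz), "zero-variance.*3")
})

test_that("snv standardizes rows and is idempotent", {
    expect_equal(snv(matrix(1:3, 1))[1, ], c(-1, 0, 1))
    set.seed(5)
    X <- matrix(rnorm(100), 5)
    S <- snv(X)
    oracle <- t(apply(X, 1, function(x) (x - mean(x)) / sd(x)))
    expect_equal(S, oracle)
    expect_equal(rowMeans(S), rep(0, 5), tolerance = 1e-10)
    expect_equal(apply(S, 1, sd), rep(1, 5), tolerance = 1e-10)
    expect_equal(snv(S), S, tolerance = 1e-10)
    expect_error(snv(rbind(X, 1)), "row.*6")
})

test_that("msc inverts affine scatter distortions exactly", {
    set.seed(6)
    r <- sin(seq(0, 3, length.out = 40)) + 2
    gains <- c(0.5, 1, 1.8, 2.5)
    offs <- c(-0.3, 0, 0.2, 1)
    X <- t(vapply(1:4, function(i) gains[i] * r + offs[i], numeric(40)))
    res <- msc(X, reference = r)
    for (i in 1:4) expect_equal(res$X[i, ], r, tolerance = 1e-8)
    ## the reference itself is unchanged (a = 0, b = 1)
    expect_equal(msc(matrix(r, 1), reference = r)$X[1, ], r)
    ## per-row slopes and intercepts match a least-squares oracle
    Xr <- matrix(rnorm(120), 3)
    ref <- colMeans(Xr)
    res2 <- msc(Xr)
    expect_equal(res2$reference, ref)
    for (i in 1:3) {
        ab <- coef(lm(Xr[i, ] ~ ref))
        expect_equal(res2$X[i, ], (Xr[i, ] - ab[1]) / ab[2],
                     ignore_attr = TRUE)
    }
    expect_error(msc(Xr, reference = rep(1, 40)), "zero variance")
})

test_that("savitzky-golay reproduces polynomials and local fits", {
    x <- seq_len(31)
    ## smoothing leaves a polynomial of the fitted degree unchanged
    pol <- 2 - 3 * x + 0.25 * x^2
    sm <- savitzkyGolay(matrix(pol, 1), window = 7, polyorder = 2)
    expect_equal(sm[1, ], pol, tolerance = 1e-8)
    ## first derivative of a ramp is its slope everywhere in the interior
    ramp <- 5 + 3 * x
    d1 <- savitzkyGolay(matrix(ramp, 1), 7, 2, deriv = 1)
    expect_equal(d1[1, 4:28], rep(3, 25), tolerance = 1e-8)
    ## derivative scaling by the axis spacing
    d1s <- savitzkyGolay(matrix(ramp, 1), 7, 2, deriv = 1, spacing = 0.5)
    expect_equal(d1s[1, 16], 6, tolerance = 1e-8)

    ## interior points match per-point local polynomial least squares
    set.seed(7)
    y <- sin(x / 4) + rnorm(31, 0, 0.05)
    d <- savitzkyGolay(matrix(y, 1), 7, 2, deriv = 1)
    for (j in c(4, 15, 28)) {
        w <- (j - 3):(j + 3)
        fit <- lm(y[w] ~ poly(w - j, 2, raw = TRUE))
        expect_equal(d[1, j], unname(coef(fit)[2]), tolerance = 1e-8)
    }
    ## boundary: shrink-window fit, e.g. second point uses a 3-point window
    d0 <- savitzkyGolay(matrix(y, 1), 7, 2, deriv = 0)
    fit2 <- lm(y[1:3] ~ poly(1:3 - 2, 2, raw = TRUE))
    expect_equal(d0[1, 2], unname(coef(fit2)[1]), tolerance = 1e-8)

    expect_error(savitzkyGolay(matrix(y, 1), 6, 2), "odd")
    expect_error(savitzkyGolay(matrix(y, 1), 3, 3), "exceed")
    expect_error(savitzkyGolay(matrix(y, 1), 7, 2, deriv = 3), "deriv")
})

test_that("pipelines compose operators and replay training statistics", {
    set.seed(8)
    X <- matrix(rnorm(360), 12)
    ## empty step list is the identity
    expect_equal(applyPreprocess(X, list())$spectra, X)
    ## composition equals applying the operators by hand
    cfg <- preprocessConfig(list("snv", "mean_center"))
    r <- applyPreprocess(X, cfg)
    expect_equal(r$spectra, meanCenter(snv(X))$X)
    ## the replay on new data uses the training statistics
    Xnew <- matrix(rnorm(90), 3)
    rp <- applyPreprocess(Xnew, cfg, state = r$state)
    expect_equal(rp$spectra, sweep(snv(Xnew), 2, colMeans(snv(X))))
    ## SpectraSet in, SpectraSet out, with derivative spacing from the axis
    s <- randomSpectraSet(6, 40, seed = 9)
    cfg2 <- preprocessConfig(list(
        list("savitzky_golay", window = 7, polyorder = 2, deriv = 1),
        "mean_center"))
    rs <- applyPreprocess(s, cfg2)
    expect_s4_class(rs$spectra, "SpectraSet")
    expect_equal(
        spectra(rs$spectra),
        meanCenter(savitzkyGolay(spectra(s), 7, 2, 1, spacing = 1))$X,
        ignore_attr = TRUE)
    ## errors are tagged with the failing step
    expect_error(applyPreprocess(rbind(X, 0), list("snv", "mean_center")),
                 "step 1 \\(snv\\)")
    expect_error(preprocessConfig(list("detrend")), "unknown")
})
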