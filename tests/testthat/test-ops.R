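test_that("ops prefix schedule follows window/increment arithmetic", {
    d <- plantedData(n = 30, p = 20, signal = 1:3, noise = 0.2)
    v <- informativeVector(d$X, d$y, "COR", 2)
    r <- opsRun(d$X, d$y, v, window = 5, increment = 5, folds = 5,
                hModel = 2)
    expect_identical(r$sizes, c(5L, 10L, 15L, 20L))
    ## p = window: a single candidate containing every variable
    r1 <- opsRun(d$X, d$y, v, window = 20, increment = 5, folds = 5,
                 hModel = 2)
    expect_identical(r1$sizes, 20L)
    expect_identical(r1$chosen, 1:20)
    ## the full set is appended when the schedule misses it
    r2 <- opsRun(d$X, d$y, v, window = 6, increment = 9, folds = 5,
                 hModel = 2)
    expect_identical(r2$sizes, c(6L, 15L, 20L))
})

test_that("ops evaluation equals the public cross-validation on a prefix", {
    set.seed(61)
    d <- plantedData(n = 40, p = 15, signal = c(1, 5, 9), noise = 0.3)
    v <- informativeVector(d$X, d$y, "COR", 3)
    r <- opsRun(d$X, d$y, v, window = 6, increment = 3, folds = 5,
                hModel = 3)
    ## rebuild each candidate score with crossValidatePLS on the same folds
    for (i in seq_along(r$sizes)) {
        idx <- r$ranking[seq_len(r$sizes[i])]
        cv <- crossValidatePLS(d$X[, idx, drop = FALSE], d$y, maxLv = 3,
                               folds = 5)
        expect_equal(r$rmsecv[i], cv$rmsecv[3], tolerance = 1e-10)
    }
    ## chosen subset: minimal RMSECV, reported sorted in original coords
    expect_identical(r$chosenRmsecv, min(r$rmsecv))
    expect_identical(r$chosen, sort(r$chosen))
    expect_false(anyDuplicated(r$chosen) > 0)
})

test_that("selection beats or matches the full set under the same CV", {
    set.seed(62)
    d <- plantedData(n = 50, p = 40, signal = 1:6, noise = 1)
    res <- autoOPS(d$X, d$y, hVec = 3, hModel = 3, folds = 5)
    full <- crossValidatePLS(d$X, d$y, maxLv = 3, folds = 5)
    expect_lte(res$chosenRmsecv, full$rmsecv[3] + 1e-12)
    ## the winner is the argmin over all per-vector runs
    expect_lte(res$chosenRmsecv, min(res$summary$rmsecv) + 1e-12)
})

test_that("autoOPS recovers planted informative bands", {
    recovered <- numeric(10)
    for (s in 1:10) {
        set.seed(s + 200)
        d <- plantedData(n = 50, p = 40, signal = 11:20, noise = 0.5,
                         seed = s + 200)
        res <- autoOPS(d$X, d$y, hVec = 4, hModel = 4, folds = 5)
        recovered[s] <- mean(d$signal %in% res$chosen)
    }
    expect_gte(mean(recovered), 0.8)
})

test_that("autoOPS is deterministic and breaks ties lexicographically", {
    d <- plantedData(n = 35, p = 16, signal = c(2, 7), noise = 0.4)
    r1 <- autoOPS(d$X, d$y, hVec = 2, hModel = 2, folds = 5)
    r2 <- autoOPS(d$X, d$y, hVec = 2, hModel = 2, folds = 5)
    expect_identical(r1$chosen, r2$chosen)
    expect_identical(r1$kind, r2$kind)
    ## identical candidate vectors give identical runs; the reported
    ## winner is the lexicographically first kind
    v <- informativeVector(d$X, d$y, "COR", 2)
    ra <- opsRun(d$X, d$y, v, 4, 4, folds = 5, hModel = 2)
    vb <- v; vb$kind <- "ZZZ"
    rb <- opsRun(d$X, d$y, vb, 4, 4, folds = 5, hModel = 2)
    expect_identical(ra$chosen, rb$chosen)
    expect_identical(ra$rmsecv, rb$rmsecv)
})

test_that("feedOPS iterates to a fixed point without losing ground", {
    set.seed(63)
    d <- plantedData(n = 45, p = 30, signal = c(3, 9, 21), noise = 0.5)
    res <- feedOPS(d$X, d$y, hVec = 3, hModel = 3, folds = 5,
                   maxRounds = 4)
    expect_identical(res$method, "feedOPS")
    ## subset sizes never grow across rounds and the final RMSECV does
    ## not exceed round 1's
    expect_true(all(diff(res$rounds$nVars) <= 0))
    expect_lte(res$chosenRmsecv, res$rounds$rmsecv[1] + 1e-12)
    ## indices stay valid original coordinates
    expect_true(all(res$chosen %in% seq_len(30)))
})

test_that("iOPS consults every interval and reports original indices", {
    set.seed(64)
    d <- plantedData(n = 45, p = 30, signal = 25:30, noise = 0.3)
    res <- iOPS(d$X, d$y, intervalSize = 10, hVec = 3, hModel = 3,
                folds = 5)
    expect_identical(res$method, "iOPS")
    expect_length(res$intervals, 3L)
    ## final subset lies inside the union of per-interval selections
    pool <- sort(unique(unlist(lapply(res$intervals, `[[`, "selected"))))
    expect_true(all(res$chosen %in% pool))
    ## the planted band (last interval) is represented in the final subset
    expect_gte(mean(d$signal %in% res$chosen), 0.8)
    ## intervalSize = p degenerates to selection over the whole axis
    resFull <- iOPS(d$X, d$y, intervalSize = 30, hVec = 3, hModel = 3,
                    folds = 5)
    expect_length(resFull$intervals, 1L)
    expect_true(all(resFull$chosen %in%
                    resFull$intervals[[1]]$selected))
})
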