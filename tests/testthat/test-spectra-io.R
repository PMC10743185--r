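test_that("SpectraSet construction validates and orients the axis", {
    X <- matrix(seq_len(15), 3, 5)
    s <- SpectraSet(X, seq(1000, 1400, 100))
    expect_identical(dim(spectra(s)), c(3L, 5L))
    expect_identical(wavelengths(s), seq(1000, 1400, 100))
    expect_null(concentrations(s))

    ## descending axis (cm-1 style) is reversed together with the columns
    sd <- SpectraSet(X, seq(5000, 4000, -250), unit = "cm-1")
    expect_identical(wavelengths(sd), seq(4000, 5000, 250))
    expect_equal(spectra(sd)[, 1], as.numeric(X[, 5]), ignore_attr = TRUE)

    expect_error(SpectraSet(X, 1:4), "wavelengths")
    expect_error(SpectraSet(X, c(1000, 1000, 1100, 1200, 1300)),
                 "increasing")
    expect_error(SpectraSet(X, seq(1000, 1400, 100),
                            ids = c("a", "a", "b")), "duplicate")
    expect_error(SpectraSet(X, seq(1000, 1400, 100),
                            concentrations = c(1, 2)), "concentrations")
})

test_that("unit conversion is the 1e7/x involution and keeps data", {
    s <- randomSpectraSet(3, 6, seed = 2)
    w <- convertWavelengthUnit(s, "cm-1")
    expect_identical(wavelengthUnit(w), "cm-1")
    expect_equal(sort(1e7 / wavelengths(w)), wavelengths(s))
    back <- convertWavelengthUnit(w, "nm")
    expect_equal(wavelengths(back), wavelengths(s))
    expect_equal(spectra(back), spectra(s))
})

test_that("reflectance import applies log10(1/R)", {
    R <- matrix(c(0.5, 0.1, 1, 0.25), 2)
    s <- SpectraSet(R, c(1100, 1200))
    a <- reflectanceToAbsorbance(s)
    expect_equal(spectra(a), log10(1 / R), ignore_attr = TRUE)
    expect_error(reflectanceToAbsorbance(SpectraSet(-R, c(1100, 1200))),
                 "positive")
})

test_that("write/read round trip reproduces spectra to full precision", {
    s <- randomSpectraSet(10, 50, seed = 7)
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(s, path)
    s2 <- readSpectra(path)
    expect_equal(spectra(s2), spectra(s), tolerance = 0)
    expect_equal(concentrations(s2), concentrations(s), tolerance = 0)
    expect_identical(sampleIds(s2), sampleIds(s))

    ## second save of the loaded object is byte-identical
    path2 <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(s2, path2)
    expect_identical(readBin(path, "raw", file.size(path)),
                     readBin(path2, "raw", file.size(path2)))

    ## no y column when concentrations are absent
    s3 <- randomSpectraSet(3, 4, withY = FALSE)
    writeSpectra(s3, path)
    expect_false(grepl(",y$", readLines(path)[1]))
    expect_null(concentrations(readSpectra(path)))
})

test_that("malformed files fail with informative parse errors", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,1000,1100,y", "a,1,2,0.1", "b,1,2"), path)
    expect_error(readSpectra(path), "ragged row at line 3")
    writeLines(c("id,1000,1100", "a,1,x"), path)
    expect_error(readSpectra(path), "non-numeric cell at line 2")
    writeLines(c("id,1000,1100", "a,1,2", "a,3,4"), path)
    expect_error(readSpectra(path), "duplicate")
    expect_error(readSpectra(tempfile()), "not found")
})

test_that("averageReplicates means rows per group and guards y", {
    X <- rbind(rep(0, 4), rep(2, 4), rep(4, 4))
    s <- SpectraSet(X, 1:4 + 1000, ids = c("a1", "a2", "b1"),
                    concentrations = c(0.1, 0.1, 0.2))
    g <- c(a1 = "A", a2 = "A", b1 = "B")
    avg <- averageReplicates(s, g)
    expect_identical(sampleIds(avg), c("A", "B"))
    expect_equal(spectra(avg)[1, ], rep(1, 4))
    expect_equal(concentrations(avg), c(0.1, 0.2))

    ## identical replicates: idempotent; singleton groups: identity
    same <- SpectraSet(X[c(1, 1, 1), ], 1:4 + 1000,
                       ids = c("r1", "r2", "r3"))
    m <- averageReplicates(same, c(r1 = "S", r2 = "S", r3 = "S"))
    expect_equal(spectra(m)[1, ], X[1, ])
    ids <- sampleIds(s)
    single <- averageReplicates(s, setNames(ids, ids))
    expect_equal(spectra(single), spectra(s))

    ## random groups match a brute-force column-mean oracle
    set.seed(3)
    Xr <- matrix(rnorm(36), 9)
    sr <- SpectraSet(Xr, 1:4 + 1000, ids = paste0("r", 1:9))
    gr <- setNames(rep(c("G1", "G2", "G3"), each = 3), paste0("r", 1:9))
    ar <- averageReplicates(sr, gr)
    for (k in 1:3)
        expect_equal(spectra(ar)[k, ],
                     colMeans(Xr[(3 * k - 2):(3 * k), ]))

    expect_error(averageReplicates(s, g[-1]), "missing")
    bad <- SpectraSet(X, 1:4 + 1000, ids = c("a1", "a2", "b1"),
                      concentrations = c(0.1, 0.3, 0.2))
    expect_error(averageReplicates(bad, g), "conflicting")
})
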