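## Default constituent set: a low-concentration phenolic analyte with
## overtone/combination bands at 1420 / 1959 / 2140 nm, a dominant
## water-like interferent (1460 / 1920 nm O-H bands), two broad matrix
## components that overlap the analyte bands, and eight minor background
## constituents spread over the rest of the axis (their independent
## concentrations give the uninformative regions structured variance, as
## the many minor absorbers of real plant tissue do).
.defaultComponents <- function() {
    bands <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE,
                                  dimnames = list(NULL,
                                      c("center", "width", "amplitude")))
    comps <- list(
        list(name = "analyte", conc = c(0.05, 0.20),
             bands = bands(1420, 25, 0.30,
                           1959, 30, 0.35,
                           2140, 30, 0.25)),
        list(name = "water", conc = c(0.85, 1.00),
             bands = bands(1460, 40, 0.90,
                           1920, 50, 1.20)),
        list(name = "matrixA", conc = c(0.20, 0.50),
             bands = bands(1200, 35, 0.40,
                           1780, 40, 0.30,
                           2280, 45, 0.50)),
        list(name = "matrixB", conc = c(0.10, 0.30),
             bands = bands(1510, 30, 0.30,
                           2050, 40, 0.35,
                           2350, 40, 0.20)))
    ctr <- c(1210, 1340, 1550, 1700, 1860, 2040, 2250, 2320)
    for (i in seq_along(ctr))
        comps[[length(comps) + 1L]] <-
            list(name = sprintf("background%02d", i), conc = c(0, 0.15),
                 bands = bands(ctr[i], 25, 0.30))
    comps
}

#' Define a synthetic FT-NIR scenario
#'
#' Describes a Beer-Lambert mixture of Gaussian-band components on a
#' uniform wavelength grid, with optional per-sample baseline drift
#' (polynomial, degree <= 2), multiplicative scatter gain and additive
#' iid noise. The default scenario emulates a diffuse-reflectance
#' FT-NIR study of a phenolic analyte in fresh plant tissue on a
#' 1000-2500 nm axis: a low-concentration analyte (uniform 0.05-0.20
#' mg/g) with overtone / combination bands near 1420, 1959 and 2140 nm,
#' a dominant water-like interferent (strong 1460 / 1920 nm O-H bands),
#' two broad matrix components, eight minor background constituents
#' giving the uninformative regions structured variance, and noise that
#' grows toward the detector-range edges. These conditions reproduce the
#' practical regime in which full-spectrum models are degraded by
#' uninformative variables and variable selection pays off.
#'
#' @param nSamples number of samples (default 260).
#' @param nPoints grid points (default 1000).
#' @param wlRange wavelength range in nm.
#' @param components list of components, each
#'   `list(name=, conc = c(min, max), bands = matrix(center, width,
#'   amplitude))` with uniform concentration draws; `NULL` uses the
#'   default constituent set described above.
#' @param analyte index of the analyte component.
#' @param noiseSd additive noise standard deviation (absorbance units).
#' @param edgeNoise list describing the wavelength dependence of the
#'   noise: detector sensitivity falls off toward the ends of the
#'   spectral range, so the per-wavelength noise standard deviation is
#'   `noiseSd` multiplied by a profile that ramps smoothly (logistic,
#'   scale `width` nm) from 1 inside `[below, above]` up to `factor` at
#'   the extremes. `NULL` (or `factor = 1`) keeps the noise homoscedastic.
#' @param baselineSd standard deviations of the per-sample polynomial
#'   baseline coefficients (intercept, slope, curvature over the
#'   normalized axis); `c(0, 0, 0)` disables drift.
#' @param scatterSd standard deviation of the per-sample multiplicative
#'   gain (0 disables scatter).
#' @return a `NIRScenario` (classed list).
#' @export
nirScenario <- function(nSamples = 260L, nPoints = 1000L,
                        wlRange = c(1000, 2500), components = NULL,
                        analyte = 1L, noiseSd = 0.002,
                        baselineSd = c(0.01, 0.005, 0.003),
                        scatterSd = 0.02,
                        edgeNoise = list(factor = 7, below = 1150,
                                         above = 2350, width = 50)) {
    if (is.null(components)) components <- .defaultComponents()
    spec <- list(nSamples = as.integer(nSamples),
                 nPoints = as.integer(nPoints),
                 wlRange = as.numeric(wlRange), components = components,
                 analyte = as.integer(analyte), noiseSd = noiseSd,
                 baselineSd = rep_len(as.numeric(baselineSd), 3L),
                 scatterSd = scatterSd, edgeNoise = edgeNoise)
    for (cmp in components) {
        if (any(cmp$bands[, "center"] < wlRange[1]) ||
            any(cmp$bands[, "center"] > wlRange[2]))
            stop("band center outside the wavelength grid")
        if (any(cmp$bands[, "width"] <= 0)) stop("band widths must be > 0")
    }
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    ay <- components[[spec$analyte]]$conc
    if (ay[1] <= 0) stop("analyte concentrations must be positive")
    class(spec) <- "NIRScenario"
    spec
}

#' @export
print.NIRScenario <- function(x, ...) {
    cat(sprintf("NIR scenario: %d samples, %d points %.6g-%.6g nm, %d components (analyte: %s)\n",
                x$nSamples, x$nPoints, x$wlRange[1], x$wlRange[2],
                length(x$components), x$components[[x$analyte]]$name))
    invisible(x)
}

.scenarioGrid <- function(spec)
    seq(spec$wlRange[1], spec$wlRange[2], length.out = spec$nPoints)

## Per-wavelength noise multiplier: logistic ramps from 1 inside the
## high-sensitivity region up to `factor` at the range extremes.
.noiseProfile <- function(spec) {
    wl <- .scenarioGrid(spec)
    en <- spec$edgeNoise
    if (is.null(en) || is.null(en$factor) || en$factor == 1)
        return(rep(1, length(wl)))
    ramp <- stats::plogis((en$below - wl) / en$width) +
        stats::plogis((wl - en$above) / en$width)
    1 + (en$factor - 1) * ramp
}

#' Pure component spectra of a scenario
#'
#' Each component's spectrum is the sum of its Gaussian bands
#' `amplitude * exp(-(wl - center)^2 / (2 width^2))` on the grid.
#' Deterministic (no randomness).
#'
#' @param spec a [nirScenario()].
#' @return components x wavelengths matrix (row names = component names).
#' @export
pureSpectra <- function(spec) {
    stopifnot(inherits(spec, "NIRScenario"))
    wl <- .scenarioGrid(spec)
    S <- t(vapply(spec$components, function(cmp) {
        s <- numeric(length(wl))
        for (b in seq_len(nrow(cmp$bands)))
            s <- s + cmp$bands[b, "amplitude"] *
                exp(-(wl - cmp$bands[b, "center"])^2 /
                    (2 * cmp$bands[b, "width"]^2))
        s
    }, numeric(length(wl))))
    rownames(S) <- vapply(spec$components, `[[`, character(1), "name")
    S
}

#' Generate a synthetic NIR dataset with known ground truth
#'
#' Draws per-sample concentrations uniformly over each component's range
#' and builds `X = C S + baseline + gain * (C S) + noise`. Reference
#' values are the analyte column of C; the ground-truth informative
#' variables are the grid indices within 2 band widths of any analyte
#' band center (a property of the scenario geometry, independent of the
#' seed).
#'
#' @param spec a [nirScenario()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list with `spectra` (a [SpectraSet-class] carrying the analyte
#'   concentrations), `truth` (informative variable indices),
#'   `concentrations` (full C matrix) and `pure` (the S matrix).
#' @export
simulateNIR <- function(spec, seed = 1L) {
    stopifnot(inherits(spec, "NIRScenario"))
    S <- pureSpectra(spec)
    wl <- .scenarioGrid(spec)
    n <- spec$nSamples; p <- spec$nPoints
    k <- length(spec$components)
    withSeed(seed, {
        C <- vapply(spec$components, function(cmp)
            stats::runif(n, cmp$conc[1], cmp$conc[2]), numeric(n))
        M <- C %*% S
        gain <- if (spec$scatterSd > 0)
            stats::rnorm(n, 0, spec$scatterSd) else numeric(n)
        u <- (wl - spec$wlRange[1]) / diff(spec$wlRange)
        B <- cbind(stats::rnorm(n, 0, spec$baselineSd[1]),
                   stats::rnorm(n, 0, spec$baselineSd[2]),
                   stats::rnorm(n, 0, spec$baselineSd[3])) %*%
            rbind(rep(1, p), u, u^2)
        prof <- .noiseProfile(spec)
        X <- M + gain * M + B +
            matrix(stats::rnorm(n * p, 0, spec$noiseSd), n, p,
                   byrow = FALSE) * rep(prof, each = n)
    })
    ab <- spec$components[[spec$analyte]]$bands
    truth <- sort(unique(unlist(lapply(seq_len(nrow(ab)), function(b)
        which(abs(wl - ab[b, "center"]) <= 2 * ab[b, "width"])))))
    sset <- SpectraSet(X, wl, ids = sprintf("S%03d", seq_len(n)),
                       concentrations = C[, spec$analyte], unit = "nm")
    list(spectra = sset, truth = truth, concentrations = C, pure = S)
}
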