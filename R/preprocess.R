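#' Mean-center spectral variables
#'
#' Subtracts per-column means. When `center` is supplied (replaying a
#' calibration fit on prediction spectra) those means are subtracted
#' instead of the matrix's own.
#'
#' @param X numeric matrix, samples in rows.
#' @param center optional stored column means.
#' @return list with `X` (transformed matrix) and `center` (means used).
#' @export
meanCenter <- function(X, center = NULL) {
    X <- as.matrix(X)
    if (is.null(center)) {
        center <- colMeans(X)
    } else if (length(center) != ncol(X)) {
        stop("stored means have length ", length(center),
             " but X has ", ncol(X), " columns")
    }
    list(X = sweep(X, 2L, center, "-"), center = center)
}

#' Autoscale spectral variables
#'
#' Column-wise standardization to mean 0 and sample (n-1) standard
#' deviation 1. Fitted statistics are returned so prediction spectra can
#' be transformed identically.
#'
#' @param X numeric matrix, samples in rows.
#' @param center,scale optional stored means and standard deviations.
#' @return list with `X`, `center`, `scale`.
#' @export
autoscale <- function(X, center = NULL, scale = NULL) {
    X <- as.matrix(X)
    if (is.null(center) != is.null(scale))
        stop("supply both 'center' and 'scale', or neither")
    if (is.null(center)) {
        center <- colMeans(X)
        scale <- apply(X, 2L, stats::sd)
        zero <- which(scale == 0)
        if (length(zero))
            stop("zero-variance column(s) at index ",
                 paste(zero, collapse = ", "))
    } else if (length(center) != ncol(X) || length(scale) != ncol(X)) {
        stop("stored statistics do not match the column count")
    }
    Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
    list(X = Xs, center = center, scale = scale)
}

#' Standard normal variate transform
#'
#' Each spectrum (row) is standardized to mean 0 and sample standard
#' deviation 1. Purely row-wise: no calibration statistics exist, the
#' same operator applies to any spectrum.
#'
#' @param X numeric matrix, samples in rows.
#' @return the transformed matrix.
#' @export
snv <- function(X) {
    X <- as.matrix(X)
    m <- rowMeans(X)
    s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1L))
    bad <- which(s == 0)
    if (length(bad))
        stop("constant spectrum in row(s) ", paste(bad, collapse = ", "))
    (X - m) / s
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on the reference spectrum r by ordinary
#' least squares, x ~ a + b * r, and replaced by (x - a) / b. The
#' reference defaults to the column-mean spectrum of the fitted set and
#' is returned so new spectra can be corrected against the calibration
#' reference.
#'
#' @param X numeric matrix, samples in rows.
#' @param reference optional stored reference spectrum.
#' @return list with `X` and `reference`.
#' @export
msc <- function(X, reference = NULL) {
    X <- as.matrix(X)
    if (is.null(reference)) reference <- colMeans(X)
    if (length(reference) != ncol(X))
        stop("reference length does not match the column count")
    rc <- reference - mean(reference)
    vr <- sum(rc^2)
    if (vr == 0) stop("reference spectrum has zero variance")
    b <- as.vector(X %*% rc) / vr           # slope of x ~ a + b r
    a <- rowMeans(X) - b * mean(reference)
    list(X = (X - a) / b, reference = reference)
}

## Shrink-window polynomial fit for one boundary point: symmetric window
## of halfwidth hw around index i, polynomial order capped below the
## window width.
.sgEdgeCoef <- function(hw, polyorder, deriv, spacing) {
    off <- (-hw):hw
    ord <- min(polyorder, 2L * hw)
    A <- outer(off, 0:ord, "^")
    Ct <- solve(crossprod(A), t(A))          # row d+1 -> d-th derivative
    Ct[deriv + 1L, ] * factorial(deriv) / spacing^deriv
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Row-wise Savitzky-Golay filtering: each point is replaced by the value
#' (or `deriv`-th derivative) of a local least-squares polynomial of
#' order `polyorder` over a window of `window` points. Interior
#' coefficients come from [signal::sgolay()]; boundary points use a
#' symmetric window shrunk to fit (with the polynomial order capped by
#' the shrunk width), so the output keeps the input width and selection
#' indices remain valid.
#'
#' @param X numeric matrix, samples in rows.
#' @param window odd window length, `> polyorder`.
#' @param polyorder polynomial order.
#' @param deriv derivative order, 0, 1 or 2; derivative values are scaled
#'   by `spacing^-deriv`.
#' @param spacing wavelength step of the (uniform) axis; required for
#'   `deriv > 0` interpretation in per-nm units.
#' @return the filtered matrix.
#' @export
savitzkyGolay <- function(X, window, polyorder, deriv = 0L, spacing = 1) {
    X <- as.matrix(X)
    window <- as.integer(window); polyorder <- as.integer(polyorder)
    deriv <- as.integer(deriv)
    if (window %% 2L != 1L) stop("'window' must be odd")
    if (window <= polyorder) stop("'window' must exceed 'polyorder'")
    if (!deriv %in% 0:2) stop("'deriv' must be 0, 1 or 2")
    if (deriv > polyorder) stop("'deriv' must not exceed 'polyorder'")
    if (ncol(X) < window) stop("fewer columns than the filter window")
    if (spacing <= 0) stop("'spacing' must be positive")
    half <- (window - 1L) %/% 2L
    Fm <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = spacing)
    ccent <- Fm[half + 1L, ]
    p <- ncol(X)
    out <- matrix(0, nrow(X), p)
    ## interior: convolution with the central coefficient row
    idx <- (half + 1L):(p - half)
    for (j in idx)
        out[, j] <- X[, (j - half):(j + half), drop = FALSE] %*% ccent
    ## edges: shrink-window fits
    for (j in seq_len(half)) {
        jr <- p - j + 1L
        if (j == 1L && deriv > 0L) {
            out[, c(j, jr)] <- NA       # 1-point window has no derivative
            next
        }
        cl <- .sgEdgeCoef(j - 1L, polyorder, deriv, spacing)
        out[, j] <- X[, 1L:(2L * j - 1L), drop = FALSE] %*% cl
        out[, jr] <- X[, (p - 2L * j + 2L):p, drop = FALSE] %*% cl
    }
    ## a 1-point window has no derivative: extrapolate from the neighbour
    if (deriv > 0L) {
        out[, 1L] <- out[, 2L]
        out[, p] <- out[, p - 1L]
    }
    out
}

.preprocOps <- c("mean_center", "autoscale", "snv", "msc", "savitzky_golay")

#' Validate a preprocessing step list
#'
#' Steps are applied in order by [applyPreprocess()]. Each step is either
#' an operator name or `list(<name>, <param>=...)`; supported operators
#' are `mean_center`, `autoscale`, `snv`, `msc` and
#' `savitzky_golay` (parameters `window`, `polyorder`, `deriv`).
#'
#' @param steps list (or character vector) of steps.
#' @return the normalized step list (class `PreprocessConfig`).
#' @examples
#' preprocessConfig(list(list("savitzky_golay", window = 11, polyorder = 2,
#'                            deriv = 1), "mean_center"))
#' @export
preprocessConfig <- function(steps) {
    if (is.character(steps)) steps <- as.list(steps)
    steps <- lapply(steps, function(st) {
        if (is.character(st) && length(st) == 1L) st <- list(st)
        name <- st[[1L]]
        if (!name %in% .preprocOps)
            stop("unknown preprocessing operator '", name, "'")
        pars <- st[-1L]
        if (name == "savitzky_golay") {
            pars$window <- as.integer(pars$window %||% 11L)
            pars$polyorder <- as.integer(pars$polyorder %||% 2L)
            pars$deriv <- as.integer(pars$deriv %||% 0L)
            if (pars$window %% 2L != 1L || pars$window <= pars$polyorder)
                stop("savitzky_golay window must be odd and > polyorder")
            if (!pars$deriv %in% 0:2)
                stop("savitzky_golay deriv must be 0, 1 or 2")
        }
        c(list(name = name), pars)
    })
    structure(steps, class = "PreprocessConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a preprocessing pipeline
#'
#' Runs the configured steps in order. On a calibration set (no `state`)
#' every training statistic (column means/scales, MSC reference) is
#' captured and returned; passing that `state` back replays the identical
#' transform on prediction spectra. For `savitzky_golay` derivatives the
#' wavelength spacing is taken from the axis, which must be uniform.
#'
#' @param s a [SpectraSet-class] or bare matrix (samples in rows).
#' @param config a [preprocessConfig()] (or the raw step list).
#' @param state optional fitted state from a previous call.
#' @return list with `spectra` (same type as the input) and `state`.
#' @export
applyPreprocess <- function(s, config, state = NULL) {
    if (!inherits(config, "PreprocessConfig"))
        config <- preprocessConfig(config)
    isSet <- is(s, "SpectraSet")
    X <- if (isSet) spectra(s) else as.matrix(s)
    spacing <- 1
    if (isSet && length(wavelengths(s)) > 1L) {
        d <- diff(wavelengths(s))
        spacing <- d[1L]
        if (any(abs(d - spacing) > 1e-8 * abs(spacing))) spacing <- NA
    }
    fitting <- is.null(state)
    if (fitting) state <- vector("list", length(config))
    for (k in seq_along(config)) {
        st <- config[[k]]
        res <- tryCatch(switch(st$name,
            mean_center = {
                r <- meanCenter(X, center = state[[k]]$center)
                state[[k]] <- list(center = r$center); r$X
            },
            autoscale = {
                r <- autoscale(X, center = state[[k]]$center,
                               scale = state[[k]]$scale)
                state[[k]] <- list(center = r$center, scale = r$scale); r$X
            },
            snv = snv(X),
            msc = {
                r <- msc(X, reference = state[[k]]$reference)
                state[[k]] <- list(reference = r$reference); r$X
            },
            savitzky_golay = {
                if (st$deriv > 0L && is.na(spacing))
                    stop("derivatives need a uniform wavelength axis")
                savitzkyGolay(X, st$window, st$polyorder, st$deriv,
                              spacing = if (is.na(spacing)) 1 else spacing)
            }), error = function(e)
                stop("preprocessing step ", k, " (", st$name, "): ",
                     conditionMessage(e), call. = FALSE))
        X <- res
    }
    out <- if (isSet)
        SpectraSet(X, wavelengths(s), ids = sampleIds(s),
                   concentrations = concentrations(s),
                   unit = wavelengthUnit(s)) else X
    list(spectra = out, state = state)
}
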