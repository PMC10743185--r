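#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SpectraSet
#'
#' @param X numeric matrix of absorbances, rows = samples, columns =
#'   wavelengths (the chemometric orientation; it is transposed into the
#'   feature-by-sample assay internally).
#' @param wavelengths numeric axis, one value per column of `X`, strictly
#'   monotone. A strictly decreasing axis (common for cm-1 files) is
#'   reversed, together with the columns of `X`.
#' @param ids sample identifiers; defaults to `rownames(X)` or `S1..Sn`.
#' @param concentrations optional per-sample analyte reference values
#'   (mg/g); must be finite and of length `nrow(X)`.
#' @param unit axis unit, `"nm"` or `"cm-1"`.
#'
#' @return a [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(rnorm(15), 3), wavelengths = seq(1000, 1400, 100))
#' dim(spectra(s))
#' @export
SpectraSet <- function(X, wavelengths, ids = NULL,
                       concentrations = NULL, unit = c("nm", "cm-1")) {
    unit <- match.arg(unit)
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (length(wavelengths) != ncol(X))
        stop("length(wavelengths) must equal ncol(X)")
    if (is.null(ids)) ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("S", seq_len(nrow(X)))
    ids <- as.character(ids)
    if (length(ids) != nrow(X))
        stop("length(ids) must equal nrow(X)")
    if (anyDuplicated(ids))
        stop("duplicate sample ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (length(wavelengths) > 1L && all(diff(wavelengths) < 0)) {
        wavelengths <- rev(wavelengths)
        X <- X[, rev(seq_len(ncol(X))), drop = FALSE]
    }
    cd <- S4Vectors::DataFrame(row.names = ids)
    if (!is.null(concentrations)) {
        if (length(concentrations) != nrow(X))
            stop("length(concentrations) must equal the sample count")
        cd$concentration <- as.numeric(concentrations)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(absorbance = t(X)),
        rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelengths)),
        colData = cd,
        metadata = list(wavelengthUnit = unit))
    out <- as(se, "SpectraSet")
    validObject(out)
    out
}

#' @describeIn SpectraSet wavelength axis (ascending).
#' @param x a `SpectraSet`.
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
    SummarizedExperiment::rowData(x)$wavelength)

#' @describeIn SpectraSet axis unit, `"nm"` or `"cm-1"`.
#' @export
setMethod("wavelengthUnit", "SpectraSet", function(x)
    S4Vectors::metadata(x)$wavelengthUnit)

#' @describeIn SpectraSet absorbance matrix, samples in rows.
#' @export
setMethod("spectra", "SpectraSet", function(x) {
    m <- t(SummarizedExperiment::assay(x, "absorbance"))
    dimnames(m) <- list(colnames(x), NULL)
    m
})

#' @describeIn SpectraSet sample identifiers.
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

#' @describeIn SpectraSet analyte reference values, or `NULL` when absent.
#' @export
setMethod("concentrations", "SpectraSet", function(x)
    SummarizedExperiment::colData(x)$concentration)

#' @describeIn SpectraSet replace the reference values (`NULL` removes them).
#' @param value numeric vector of reference values, or `NULL`.
#' @export
setReplaceMethod("concentrations", "SpectraSet", function(x, value) {
    if (!is.null(value) && length(value) != ncol(x))
        stop("length(value) must equal the sample count")
    SummarizedExperiment::colData(x)$concentration <-
        if (is.null(value)) NULL else as.numeric(value)
    validObject(x)
    x
})

setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat("SpectraSet:", ncol(object), "samples x", nrow(object),
        "wavelengths\n")
    cat(sprintf("  axis: %.6g-%.6g %s\n", min(wl), max(wl),
                wavelengthUnit(object)))
    y <- concentrations(object)
    if (is.null(y)) {
        cat("  reference concentrations: none\n")
    } else {
        cat(sprintf("  reference concentrations: %.4g-%.4g (mean %.4g)\n",
                    min(y), max(y), mean(y)))
    }
    invisible(NULL)
})

#' Average replicate spectra into per-sample spectra
#'
#' Replicate rows belonging to the same physical sample (e.g. repeated
#' scans around the terminal bud) are replaced by their arithmetic mean
#' spectrum. When reference concentrations are present they must agree
#' exactly within each group (they describe one physical sample);
#' disagreement is an error, not silently averaged away.
#'
#' @param s a [SpectraSet-class].
#' @param groups named character vector mapping every replicate id to its
#'   sample id (names = replicate ids as in `sampleIds(s)`).
#' @return a `SpectraSet` with one row per group, groups ordered by first
#'   appearance.
#' @export
averageReplicates <- function(s, groups) {
    stopifnot(is(s, "SpectraSet"))
    ids <- sampleIds(s)
    if (is.null(names(groups)))
        stop("'groups' must be named by replicate id")
    missing <- setdiff(ids, names(groups))
    if (length(missing))
        stop("replicates missing from 'groups': ",
             paste(missing, collapse = ", "))
    g <- as.character(groups[ids])
    keys <- unique(g)
    X <- spectra(s)
    y <- concentrations(s)
    Xm <- matrix(0, length(keys), ncol(X))
    ym <- if (is.null(y)) NULL else numeric(length(keys))
    for (i in seq_along(keys)) {
        rows <- which(g == keys[i])
        Xm[i, ] <- colMeans(X[rows, , drop = FALSE])
        if (!is.null(y)) {
            yy <- y[rows]
            if (max(yy) - min(yy) > 0)
                stop("conflicting reference values within group '",
                     keys[i], "'")
            ym[i] <- yy[1L]
        }
    }
    SpectraSet(Xm, wavelengths(s), ids = keys, concentrations = ym,
               unit = wavelengthUnit(s))
}

#' Convert the wavelength axis between nm and wavenumber
#'
#' Uses lambda\[nm\] = 1e7 / nu\[cm-1\] (and vice versa); the converted axis
#' is re-sorted ascending together with the spectra columns.
#'
#' @param s a [SpectraSet-class].
#' @param to target unit.
#' @return a `SpectraSet` on the converted axis.
#' @export
convertWavelengthUnit <- function(s, to = c("nm", "cm-1")) {
    to <- match.arg(to)
    if (identical(wavelengthUnit(s), to)) return(s)
    wl <- 1e7 / wavelengths(s)   # descending; constructor reverses
    SpectraSet(spectra(s), wl, ids = sampleIds(s),
               concentrations = concentrations(s), unit = to)
}

#' Convert relative reflectance to absorbance
#'
#' Applies log10(1/R) element-wise, the representation FT-NIR instruments
#' record for diffuse reflectance.
#'
#' @param s a [SpectraSet-class] holding relative reflectance values in
#'   (0, 1\].
#' @return a `SpectraSet` of absorbances.
#' @export
reflectanceToAbsorbance <- function(s) {
    R <- spectra(s)
    if (any(R <= 0))
        stop("reflectance values must be positive")
    SpectraSet(log10(1 / R), wavelengths(s), ids = sampleIds(s),
               concentrations = concentrations(s), unit = wavelengthUnit(s))
}
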