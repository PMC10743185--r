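#' SpectraSet: NIR spectra with an ordered wavelength axis
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] for
#' samples-by-wavelengths absorbance data. Following the
#' SummarizedExperiment convention, spectral variables (wavelengths) are
#' rows and samples are columns; the user-facing accessor [spectra()]
#' returns the matrix in the chemometric orientation (samples in rows).
#'
#' The single assay `"absorbance"` holds absorbance values (log(1/R)).
#' `rowData` carries the numeric `wavelength` column (strictly increasing
#' after construction; descending input axes are reversed together with
#' the matrix). `colData` optionally carries a `concentration` column with
#' the per-sample analyte reference values (mg/g). The axis unit
#' (`"nm"` or `"cm-1"`) is kept in `metadata(x)$wavelengthUnit`.
#'
#' @slot (inherited) see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [SpectraSet()], [readSpectra()], [writeSpectra()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
    msg <- character()
    if (!identical(SummarizedExperiment::assayNames(object), "absorbance"))
        msg <- c(msg, "assay must be a single matrix named 'absorbance'")
    wl <- SummarizedExperiment::rowData(object)$wavelength
    if (is.null(wl)) {
        msg <- c(msg, "rowData must contain a numeric 'wavelength' column")
    } else {
        if (!is.numeric(wl) || anyNA(wl) || any(!is.finite(wl)))
            msg <- c(msg, "wavelengths must be finite numbers")
        else if (length(wl) > 1L && any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
    }
    unit <- S4Vectors::metadata(object)$wavelengthUnit
    if (is.null(unit) || !unit %in% c("nm", "cm-1"))
        msg <- c(msg, "metadata wavelengthUnit must be 'nm' or 'cm-1'")
    ids <- colnames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    y <- SummarizedExperiment::colData(object)$concentration
    if (!is.null(y) && (!is.numeric(y) || any(!is.finite(y))))
        msg <- c(msg, "concentrations must be finite numbers")
    if (length(msg)) msg else TRUE
}
setValidity("SpectraSet", .validSpectraSet)

#' PLS1 calibration model (NIPALS)
#'
#' Holds the weights, scores and loadings of a univariate-response partial
#' least squares model together with the assembled regression vector and
#' the centering statistics, so that the model is self-contained for
#' prediction. See [fitPLS()].
#'
#' @slot nLv number of latent variables extracted.
#' @slot W p x h weight matrix, columns unit norm.
#' @slot scores n x h score matrix T, columns mutually orthogonal.
#' @slot P p x h x-loading matrix.
#' @slot q length-h y-loading vector.
#' @slot b length-p regression vector in (centered) predictor space.
#' @slot xMeans,yMean centering statistics captured at fit time.
#' @slot rmsec calibration root mean square error.
#' @export
setClass("PLSModel", representation(
    nLv = "integer", W = "matrix", scores = "matrix", P = "matrix",
    q = "numeric", b = "numeric", xMeans = "numeric", yMean = "numeric",
    rmsec = "numeric"))

.validPLSModel <- function(object) {
    msg <- character()
    h <- object@nLv
    if (ncol(object@W) != h || ncol(object@P) != h ||
        ncol(object@scores) != h || length(object@q) != h)
        msg <- c(msg, "W, P, scores and q must all have h components")
    if (nrow(object@W) != length(object@b) ||
        nrow(object@P) != length(object@b) ||
        length(object@xMeans) != length(object@b))
        msg <- c(msg, "W, P, b and xMeans must agree on the variable count")
    if (h > 0) {
        wn <- sqrt(colSums(object@W^2))
        if (any(abs(wn - 1) > 1e-8))
            msg <- c(msg, "weight columns must have unit norm")
        G <- crossprod(object@scores)
        if (max(abs(G - diag(diag(G), nrow = h))) > 1e-6 * max(diag(G)))
            msg <- c(msg, "score columns must be mutually orthogonal")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PLSModel", .validPLSModel)

#' Multiple linear regression model on selected variables
#'
#' Ordinary least squares on a small set of selected spectral variables;
#' see [fitMLR()]. Predictions read only the stored `variableIndices`
#' columns of new data.
#'
#' @slot variableIndices columns (original matrix coordinates) in the model.
#' @slot coefficients per-variable slopes, same order as `variableIndices`.
#' @slot intercept scalar intercept.
#' @export
setClass("MLRModel", representation(
    variableIndices = "integer", coefficients = "numeric",
    intercept = "numeric"))

.validMLRModel <- function(object) {
    msg <- character()
    if (length(object@coefficients) != length(object@variableIndices))
        msg <- c(msg, "one coefficient per selected variable required")
    if (anyDuplicated(object@variableIndices))
        msg <- c(msg, "variable indices must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("MLRModel", .validMLRModel)
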