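#' Coefficient of determination
#'
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2). May be negative for
#' models worse than the mean predictor.
#'
#' @param y reference values.
#' @param yhat predictions.
#' @return scalar R2.
#' @export
rSquared <- function(y, yhat) {
    if (length(y) != length(yhat)) stop("length mismatch")
    if (length(y) < 2L) stop("need at least two samples")
    ss <- sum((y - mean(y))^2)
    if (ss == 0) stop("reference values are constant")
    1 - sum((y - yhat)^2) / ss
}

#' Root mean square error
#'
#' sqrt(mean((yhat - y)^2)).
#'
#' @inheritParams rSquared
#' @return scalar RMSE.
#' @export
rmse <- function(y, yhat) {
    if (length(y) != length(yhat)) stop("length mismatch")
    sqrt(mean((yhat - y)^2))
}

#' Ratio of performance to deviation
#'
#' Sample (n-1) standard deviation of the prediction-set reference values
#' divided by RMSEP. Values below 2 are conventionally read as an
#' unacceptable calibration.
#'
#' @param yReference prediction-set reference values.
#' @param rmsep prediction root mean square error, > 0.
#' @return scalar RPD.
#' @export
rpd <- function(yReference, rmsep) {
    if (length(yReference) < 2L) stop("need at least two reference values")
    if (rmsep <= 0) stop("rmsep must be positive (RPD would be infinite)")
    stats::sd(yReference) / rmsep
}

#' Range error ratio
#'
#' (max - min) of the reference values divided by RMSEP.
#'
#' @inheritParams rpd
#' @return scalar RER.
#' @export
rer <- function(yReference, rmsep) {
    if (rmsep <= 0) stop("rmsep must be positive (RER would be infinite)")
    diff(range(yReference)) / rmsep
}

#' Per-sample relative errors
#'
#' (y - yhat) / y * 100, in percent.
#'
#' @inheritParams rSquared
#' @return numeric vector of percentages.
#' @export
relativeErrors <- function(y, yhat) {
    if (length(y) != length(yhat)) stop("length mismatch")
    bad <- which(y == 0)
    if (length(bad))
        stop("zero reference value for sample(s) ",
             paste(bad, collapse = ", "))
    (y - yhat) / y * 100
}

#' Evaluate a calibration model on calibration and prediction sets
#'
#' Computes the usual multivariate-calibration report: Rc2/RMSEC on the
#' calibration set, Rp2/RMSEP/RPD/RER and per-sample relative errors on
#' the prediction set, SEP/SEC (= RMSEP/RMSEC), plus the cross-validation
#' columns when a [crossValidatePLS()] result is supplied. The matrices
#' must already be on the model's preprocessing lineage.
#'
#' @param model a [PLSModel-class] or [MLRModel-class].
#' @param Xcal,ycal calibration spectra (samples x variables) and
#'   reference values.
#' @param Xpred,ypred prediction spectra and reference values.
#' @param cv optional `PLSCV` result contributing Rcv2/RMSECV.
#' @param rangeFrom reference range used in RER: the prediction set
#'   (default) or the pooled calibration + prediction values.
#' @return an `EvalReport` (classed list) with fields `nCal`, `nPred`,
#'   `nVars`, `LVs`, `Rc2`, `RMSEC`, `Rcv2`, `RMSECV`, `Rp2`, `RMSEP`,
#'   `RPD`, `RER`, `SEPSEC` and `RE` (per-sample prediction relative
#'   errors, %).
#' @export
evaluateModel <- function(model, Xcal, ycal, Xpred, ypred, cv = NULL,
                          rangeFrom = c("prediction", "pooled")) {
    rangeFrom <- match.arg(rangeFrom)
    Xcal <- as.matrix(Xcal); Xpred <- as.matrix(Xpred)
    yc <- predict(model, Xcal)
    yp <- predict(model, Xpred)
    rmsec <- rmse(ycal, yc)
    rmsep <- rmse(ypred, yp)
    yr <- if (rangeFrom == "prediction") ypred else c(ycal, ypred)
    rep <- list(
        nCal = length(ycal), nPred = length(ypred),
        nVars = if (is(model, "MLRModel"))
            length(model@variableIndices) else ncol(Xcal),
        LVs = if (is(model, "PLSModel")) model@nLv else NA_integer_,
        Rc2 = rSquared(ycal, yc), RMSEC = rmsec,
        Rcv2 = if (is.null(cv)) NA_real_ else cv$rcv2[cv$chosen],
        RMSECV = if (is.null(cv)) NA_real_ else cv$rmsecv[cv$chosen],
        Rp2 = rSquared(ypred, yp), RMSEP = rmsep,
        RPD = if (rmsep > 0) rpd(ypred, rmsep) else NA_real_,
        RER = if (rmsep > 0) rer(yr, rmsep) else NA_real_,
        SEPSEC = if (rmsec > 0) rmsep / rmsec else NA_real_,
        RE = relativeErrors(ypred, yp))
    class(rep) <- "EvalReport"
    rep
}

#' @export
print.EvalReport <- function(x, ...) {
    cat("Calibration model evaluation\n")
    cat(sprintf("  n (cal/pred): %d / %d   variables: %d%s\n",
                x$nCal, x$nPred, x$nVars,
                if (is.na(x$LVs)) "" else sprintf("   LVs: %d", x$LVs)))
    cat(sprintf("  Rc2 %.4f  RMSEC %.4f", x$Rc2, x$RMSEC))
    if (!is.na(x$Rcv2))
        cat(sprintf("  Rcv2 %.4f  RMSECV %.4f", x$Rcv2, x$RMSECV))
    cat("\n")
    cat(sprintf("  Rp2 %.4f  RMSEP %.4f  RPD %.2f  RER %.2f  SEP/SEC %.2f\n",
                x$Rp2, x$RMSEP, x$RPD, x$RER, x$SEPSEC))
    cat(sprintf("  |RE%%| median %.2f  max %.2f\n",
                stats::median(abs(x$RE)), max(abs(x$RE))))
    invisible(x)
}

#' Serialize / restore an evaluation report as CSV
#'
#' One row of scalar statistics at 6 significant digits plus the
#' per-sample relative errors; [readEvalReport()] restores the classed
#' list.
#'
#' @param x an `EvalReport`.
#' @param path file to write / read.
#' @return `path` invisibly; `readEvalReport` returns the report.
#' @export
writeEvalReport <- function(x, path) {
    scal <- x[setdiff(names(x), "RE")]
    lines <- c(
        paste(names(scal), collapse = ","),
        paste(vapply(scal, function(v)
            if (is.na(v)) "NA" else sprintf("%.6g", v), character(1)),
            collapse = ","),
        "RE",
        paste(sprintf("%.6g", x$RE), collapse = ","))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(path) {
    lines <- readLines(path)
    keys <- strsplit(lines[1L], ",")[[1L]]
    vals <- as.numeric(strsplit(lines[2L], ",")[[1L]])
    rep <- as.list(vals)
    names(rep) <- keys
    for (k in c("nCal", "nPred", "nVars", "LVs"))
        rep[[k]] <- as.integer(rep[[k]])
    rep$RE <- as.numeric(strsplit(lines[4L], ",")[[1L]])
    class(rep) <- "EvalReport"
    rep
}
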