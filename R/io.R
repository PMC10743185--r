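#' Read spectra from the delimited-text dialect
#'
#' The dialect is a plain CSV matrix: header row `id,<wavelength...>[,y]`,
#' then one row per spectrum (`<sample id>,<absorbance...>[,<reference>]`).
#' A trailing header cell literally named `y` marks a reference
#' concentration column. A strictly descending wavelength axis (typical
#' for cm-1 files) is reversed on load, together with the matrix columns.
#'
#' @param path file to read.
#' @param unit wavelength unit recorded on the object (`"nm"` or `"cm-1"`).
#' @param reflectance when `TRUE` the values are relative reflectance and
#'   are converted to absorbance as log10(1/R) on import.
#' @param sep field separator (default `,`).
#' @return a [SpectraSet-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, unit = c("nm", "cm-1"), reflectance = FALSE,
                        sep = ",") {
    unit <- match.arg(unit)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L) stop("file has no data rows: ", path)
    cells <- strsplit(lines, sep, fixed = TRUE)
    header <- cells[[1L]]
    nfield <- length(header)
    hasY <- identical(header[nfield], "y")
    wcols <- 2L:(nfield - hasY)
    wl <- suppressWarnings(as.numeric(header[wcols]))
    if (anyNA(wl))
        stop("non-numeric wavelength in header")
    body <- cells[-1L]
    bad <- which(lengths(body) != nfield)
    if (length(bad))
        stop("ragged row at line ", bad[1L] + 1L, ": expected ", nfield,
             " fields, found ", lengths(body)[bad[1L]])
    ids <- vapply(body, `[`, character(1), 1L)
    num <- suppressWarnings(
        vapply(body, function(r) as.numeric(r[-1L]), numeric(nfield - 1L)))
    if (anyNA(num)) {
        bad <- which(colSums(is.na(num)) > 0)[1L]
        stop("non-numeric cell at line ", bad + 1L)
    }
    num <- t(num)
    X <- num[, seq_along(wl), drop = FALSE]
    y <- if (hasY) num[, ncol(num)] else NULL
    s <- SpectraSet(X, wl, ids = ids, concentrations = y, unit = unit)
    if (reflectance) reflectanceToAbsorbance(s) else s
}

#' Write spectra in the delimited-text dialect
#'
#' Wavelengths are printed with up to 6 significant digits; absorbances
#' and reference values with 17 (so a save/load round trip reproduces the
#' matrix to full double precision and a second save is byte-identical).
#'
#' @param s a [SpectraSet-class].
#' @param path file to write.
#' @param sep field separator (default `,`).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(s, path, sep = ",") {
    stopifnot(is(s, "SpectraSet"))
    X <- spectra(s)
    y <- concentrations(s)
    header <- c("id", sprintf("%.6g", wavelengths(s)),
                if (!is.null(y)) "y")
    rows <- vapply(seq_len(nrow(X)), function(i) {
        vals <- sprintf("%.17g", X[i, ])
        if (!is.null(y)) vals <- c(vals, sprintf("%.17g", y[i]))
        paste(c(sampleIds(s)[i], vals), collapse = sep)
    }, character(1))
    con <- file(path, open = "wb")   # fixed \n endings keep saves identical
    on.exit(close(con))
    writeLines(c(paste(header, collapse = sep), rows), con, sep = "\n")
    invisible(path)
}
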