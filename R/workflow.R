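#' Configure an end-to-end calibration workflow
#'
#' Collects and validates the settings for [runWorkflow()]: the data
#' source (a [SpectraSet-class] with reference values, or a
#' [nirScenario()] to simulate), the preprocessing steps, the outlier
#' scan, the Kennard-Stone split ratio, the variable-selection chain and
#' the calibration model.
#'
#' @param spectra a `SpectraSet` with concentrations, or `NULL` to
#'   simulate from `scenario`.
#' @param scenario a `NIRScenario` used when `spectra` is `NULL`.
#' @param steps preprocessing steps for [preprocessConfig()]; default
#'   mean centering only.
#' @param ratio Kennard-Stone calibration fraction.
#' @param outliers list: `enabled`, `iterations`, `trainFraction`, `nLv`
#'   (NULL = the pilot CV choice), `k`.
#' @param selection selection chain: character vector drawn from
#'   `"autoops"`, `"feedops"`, `"iops"`, `"spa"`, applied in order, or
#'   `"none"`.
#' @param model `"pls"` or `"mlr"` (`"mlr"` requires a selection chain
#'   that leaves fewer variables than calibration samples minus one).
#' @param lv fixed latent-variable count for the final PLS model;
#'   `NULL` chooses by cross-validation.
#' @param folds cross-validation folds for model choice.
#' @param ops extra arguments passed to the OPS stage (window, increment,
#'   folds, combinations, hVec, hModel, intervalSize, maxRounds).
#' @param spa extra arguments for [spaSelect()] (minVars, maxVars,
#'   starts, validation).
#' @param seed master seed for every stochastic stage.
#' @param outDir directory for artifacts (report, selection, model,
#'   manifest); `NULL` writes nothing.
#' @return a validated `WorkflowConfig` (classed list).
#' @export
workflowConfig <- function(spectra = NULL, scenario = NULL,
                           steps = list("mean_center"), ratio = 0.75,
                           outliers = list(), selection = "none",
                           model = c("pls", "mlr"), lv = NULL,
                           folds = 10L, ops = list(), spa = list(),
                           seed = 1L, outDir = NULL) {
    model <- match.arg(model)
    if (is.null(spectra) && is.null(scenario))
        stop("supply 'spectra' or 'scenario'")
    selection <- tolower(selection)
    if (identical(selection, "none")) selection <- character(0)
    bad <- setdiff(selection, c("autoops", "feedops", "iops", "spa"))
    if (length(bad))
        stop("unknown selection stage(s): ", paste(bad, collapse = ", "))
    if (model == "mlr" && !length(selection))
        stop("MLR requires a variable-selection stage")
    o <- utils::modifyList(list(enabled = TRUE, iterations = NULL,
                                trainFraction = 0.75, nLv = NULL, k = 3),
                           outliers)
    cfg <- list(spectra = spectra, scenario = scenario,
                steps = preprocessConfig(steps), ratio = ratio,
                outliers = o, selection = selection, model = model,
                lv = lv, folds = as.integer(folds), ops = ops, spa = spa,
                seed = as.integer(seed), outDir = outDir)
    class(cfg) <- "WorkflowConfig"
    cfg
}

## Serializable echo of a config (drops the data payloads).
.configEcho <- function(cfg) {
    list(steps = lapply(unclass(cfg$steps), function(s) s),
         ratio = cfg$ratio,
         outliers = cfg$outliers[c("enabled", "trainFraction", "k")],
         outlierIterations = cfg$outliers$iterations,
         selection = as.list(cfg$selection), model = cfg$model,
         lv = cfg$lv, folds = cfg$folds, ops = cfg$ops, spa = cfg$spa,
         seed = cfg$seed,
         scenario = if (is.null(cfg$scenario)) NULL else
             cfg$scenario[c("nSamples", "nPoints", "wlRange", "analyte",
                            "noiseSd", "baselineSd", "scatterSd")])
}

#' Run the end-to-end calibration workflow
#'
#' Executes the fixed stage order: outlier scan (on the full remaining
#' sample set) -> preprocessing -> Kennard-Stone split -> variable
#' selection chain -> model fit -> evaluation. Kennard-Stone distances
#' use a provisional preprocessing fit on all retained samples (the
#' split does not exist yet); the modelling preprocessing statistics are
#' then re-fit on the calibration rows only and replayed on the
#' prediction rows, so prediction samples never contribute to the fitted
#' transform. The one documented exception to the leakage guard is the
#' SPA stage's default prediction-set-driven subset choice.
#'
#' @param cfg a [workflowConfig()].
#' @return a `WorkflowResult` (classed list): `report` (an
#'   [evaluateModel()] report), `selection` (list of per-stage
#'   `SelectionResult`/`SPAResult`s), `model`, `split`, `outliers`,
#'   `selectedWavelengths`, `cv`, `log` (one line per stage) and
#'   `manifest`. Artifacts are written under `cfg$outDir` when set.
#' @export
runWorkflow <- function(cfg) {
    stopifnot(inherits(cfg, "WorkflowConfig"))
    log <- character(0)
    note <- function(...) log <<- c(log, sprintf(...))

    ## data
    sset <- if (is.null(cfg$spectra)) {
        sim <- simulateNIR(cfg$scenario, seed = cfg$seed)
        sim$spectra
    } else cfg$spectra
    y <- concentrations(sset)
    if (is.null(y)) stop("workflow needs reference concentrations")
    X <- spectra(sset)
    note("input: %d samples x %d variables", nrow(X), ncol(X))

    ## pilot complexity for scanning / modelling defaults
    pilotLv <- function(Xm, ym) {
        maxLv <- min(15L, ncol(Xm), nrow(Xm) - ceiling(nrow(Xm) / cfg$folds) - 1L)
        crossValidatePLS(Xm, ym, maxLv = max(1L, maxLv),
                         folds = cfg$folds)$chosen
    }

    ## stage 1: outlier scan on the full set (mean-centered internally)
    od <- NULL
    if (isTRUE(cfg$outliers$enabled)) {
        nLv <- cfg$outliers$nLv %||% pilotLv(X, y)
        od <- monteCarloOutliers(X, y, nLv = nLv,
                                   iterations = cfg$outliers$iterations,
                                   trainFraction = cfg$outliers$trainFraction,
                                   seed = cfg$seed)
        od <- flagOutliers(od, k = cfg$outliers$k)
        if (length(od$flagged)) {
            X <- X[-od$flagged, , drop = FALSE]
            y <- y[-od$flagged]
        }
        note("outlier scan: %d flagged, %d samples retained",
             length(od$flagged), nrow(X))
    }

    ## stage 2/3: provisional preprocessing for KS distances, split, then
    ## calibration-only preprocessing for modelling
    prov <- applyPreprocess(X, cfg$steps)
    split <- kennardStone(prov$spectra, ratio = cfg$ratio)
    cal <- split$calibration; prd <- split$prediction
    fitP <- applyPreprocess(X[cal, , drop = FALSE], cfg$steps)
    Xcal <- fitP$spectra
    Xprd <- applyPreprocess(X[prd, , drop = FALSE], cfg$steps,
                            state = fitP$state)$spectra
    ycal <- y[cal]; yprd <- y[prd]
    note("split: %d calibration / %d prediction", length(cal), length(prd))

    ## stage 4: selection chain
    selections <- list()
    vars <- seq_len(ncol(Xcal))
    for (stage in cfg$selection) {
        Xs <- Xcal[, vars, drop = FALSE]
        res <- tryCatch(switch(stage,
            autoops = do.call(autoOPS, c(list(Xs, ycal), cfg$ops)),
            feedops = do.call(feedOPS, c(list(Xs, ycal), cfg$ops)),
            iops = do.call(iOPS, c(list(Xs, ycal),
                cfg$ops[intersect(names(cfg$ops),
                    c("intervalSize", "hVec", "hModel", "window",
                      "increment", "folds", "combinations"))])),
            spa = do.call(spaSelect, c(list(
                Xs, ycal, Xval = Xprd[, vars, drop = FALSE],
                yval = yprd), cfg$spa))),
            error = function(e) stop("selection stage '", stage, "': ",
                                     conditionMessage(e), call. = FALSE))
        prevN <- length(vars)
        vars <- sort(vars[res$chosen])
        selections[[stage]] <- res
        note("%s: %d -> %d variables", stage, prevN, length(vars))
    }

    ## stage 5: model fit on the selected variables
    Xc <- Xcal[, vars, drop = FALSE]
    Xp <- Xprd[, vars, drop = FALSE]
    cv <- NULL
    if (cfg$model == "pls") {
        maxLv <- min(15L, ncol(Xc),
                     length(ycal) - ceiling(length(ycal) / cfg$folds) - 1L)
        cv <- crossValidatePLS(Xc, ycal, maxLv = max(1L, maxLv),
                               folds = cfg$folds)
        lv <- cfg$lv %||% cv$chosen
        model <- fitPLS(Xc, ycal, nLv = min(lv, maxLv))
        note("PLS: %d latent variables on %d variables", model@nLv,
             ncol(Xc))
    } else {
        if (length(vars) >= length(ycal) - 1L)
            stop("MLR needs fewer selected variables than n_cal - 1")
        model <- fitMLR(Xc, ycal, seq_len(ncol(Xc)))
        note("MLR: %d variables", ncol(Xc))
    }

    ## stage 6: evaluation
    report <- evaluateModel(model, Xc, ycal, Xp, yprd, cv = cv)
    note("evaluation: Rp2 %.4f RMSEP %.4g", report$Rp2, report$RMSEP)

    wl <- wavelengths(sset)[vars]
    manifest <- list(package = "opsnir",
                     version = as.character(utils::packageVersion("opsnir")),
                     seed = cfg$seed, config = .configEcho(cfg),
                     stages = log,
                     nVars = length(vars))
    out <- structure(list(report = report, selection = selections,
                          model = model, split = split, outliers = od,
                          selectedVariables = vars,
                          selectedWavelengths = wl, cv = cv, log = log,
                          manifest = manifest),
                     class = "WorkflowResult")
    if (!is.null(cfg$outDir)) .writeArtifacts(out, cfg)
    out
}

.writeArtifacts <- function(res, cfg) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    writeEvalReport(res$report, file.path(cfg$outDir, "report.csv"))
    selPath <- file.path(cfg$outDir, "selection.csv")
    con <- file(selPath, open = "wb")
    writeLines(c("index,wavelength",
                 sprintf("%d,%.6g", res$selectedVariables,
                         res$selectedWavelengths)), con, sep = "\n")
    close(con)
    mPath <- file.path(cfg$outDir, "model.txt")
    con <- file(mPath, open = "wb")
    if (is(res$model, "PLSModel")) {
        writeLines(c("type: pls",
                     sprintf("nLv: %d", res$model@nLv),
                     sprintf("yMean: %.17g", res$model@yMean),
                     paste("xMeans:", paste(sprintf("%.17g",
                         res$model@xMeans), collapse = ",")),
                     paste("b:", paste(sprintf("%.17g", res$model@b),
                                       collapse = ","))), con, sep = "\n")
    } else {
        writeLines(c("type: mlr",
                     sprintf("intercept: %.17g", res$model@intercept),
                     paste("indices:", paste(res$model@variableIndices,
                                             collapse = ",")),
                     paste("coefficients:", paste(sprintf("%.17g",
                         res$model@coefficients), collapse = ","))),
                   con, sep = "\n")
    }
    close(con)
    manifest <- res$manifest
    cfgJson <- jsonlite::toJSON(manifest$config, auto_unbox = TRUE,
                                digits = NA, null = "null")
    tmp <- tempfile()
    writeLines(cfgJson, tmp)
    manifest$configHash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(NULL)
}

#' @export
print.WorkflowResult <- function(x, ...) {
    cat("Workflow result\n")
    for (l in x$log) cat(" -", l, "\n")
    print(x$report)
    invisible(x)
}
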