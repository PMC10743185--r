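.ivKinds <- c("REG", "COR", "SQR", "VIP", "NAS", "COV", "URXY", "WGHT")

#' Informative vectors for ordered predictors selection
#'
#' Computes one importance score per spectral variable. Kinds based on an
#' h-latent-variable PLS model (REG, VIP, WGHT, SQR, NAS) and kinds based
#' on simple column statistics (COR, COV, URXY):
#'
#' * `REG` — |b_j|, the PLS regression vector magnitudes.
#' * `COR` — |Pearson correlation(x_j, y)|.
#' * `COV` — |covariance(x_j, y)| (n-1 denominator).
#' * `VIP` — sqrt(p * sum_a SSa * w_ja^2 / sum_a SSa) with
#'   SSa = q_a^2 t_a't_a (weights are unit-norm), the variable importance
#'   in projection; mean squared VIP is 1 by construction.
#' * `WGHT` — sum_a |w_ja| SSa / sum_a SSa, the SS-weighted NIPALS
#'   weights.
#' * `URXY` — R2 of the univariate regression of y on x_j (squared
#'   correlation).
#' * `SQR` — per-variable explained fraction
#'   1 - ||x_j - xhat_j||^2 / ||x_j||^2 of the h-LV reconstruction
#'   Xhat = T P' (centered), the residual information carried by the
#'   latent structure.
#' * `NAS` — |b_j| * ||X b|| / ||b||^2, the per-column norm of the rank-1
#'   y-correlated (net-analyte-signal) approximation X b b'/||b||^2.
#'
#' Zero-variance columns score 0 (with a warning) for the correlation
#' kinds. Ranking for selection always uses |values| descending.
#'
#' @param X numeric matrix, samples in rows.
#' @param y reference values.
#' @param kind one of `REG`, `COR`, `SQR`, `VIP`, `NAS`, `COV`, `URXY`,
#'   `WGHT`.
#' @param h latent variables for the model-based kinds.
#' @param model optional pre-fitted [PLSModel-class] with `h` components
#'   on (X, y), to avoid refitting when several kinds are requested.
#' @return an `InformativeVector` (classed list) with `kind`, `values`
#'   (length p, finite) and `h`.
#' @export
informativeVector <- function(X, y, kind, h, model = NULL) {
    X <- as.matrix(X); y <- as.numeric(y)
    if (!kind %in% .ivKinds)
        stop("unknown informative-vector kind '", kind, "'")
    p <- ncol(X)
    needModel <- kind %in% c("REG", "VIP", "WGHT", "SQR", "NAS")
    if (needModel && is.null(model)) model <- fitPLS(X, y, h)
    vals <- switch(kind,
        REG = abs(model@b),
        COR = , URXY = {
            sds <- apply(X, 2L, stats::sd)
            zero <- sds == 0
            r <- numeric(p)
            r[!zero] <- as.vector(stats::cor(X[, !zero, drop = FALSE], y))
            if (any(zero)) warning("zero-variance column(s) scored 0")
            if (kind == "COR") abs(r) else r^2
        },
        COV = abs(as.vector(stats::cov(X, y))),
        VIP = {
            ss <- model@q^2 * colSums(model@scores^2)
            sqrt(p * as.vector(model@W^2 %*% ss) / sum(ss))
        },
        WGHT = {
            ss <- model@q^2 * colSums(model@scores^2)
            as.vector(abs(model@W) %*% ss) / sum(ss)
        },
        SQR = {
            Xc <- sweep(X, 2L, model@xMeans, "-")
            R <- Xc - model@scores %*% t(model@P)
            tot <- colSums(Xc^2)
            out <- 1 - colSums(R^2) / ifelse(tot > 0, tot, 1)
            out[tot == 0] <- 0
            out
        },
        NAS = {
            b <- model@b
            nb2 <- sum(b^2)
            if (nb2 == 0) numeric(p)
            else {
                Xc <- sweep(X, 2L, model@xMeans, "-")
                abs(b) * sqrt(sum((Xc %*% b)^2)) / nb2
            }
        })
    structure(list(kind = kind, values = as.numeric(vals),
                   h = if (needModel) model@nLv else NA_integer_),
              class = "InformativeVector")
}

## All eight base vectors (sharing one PLS fit) plus the element-wise
## products of min-max-normalized pairs, as candidate orderings for
## autoOPS.
.allInformativeVectors <- function(X, y, h, combinations = TRUE) {
    model <- fitPLS(X, y, h)
    base <- lapply(.ivKinds, function(k)
        informativeVector(X, y, k, h, model = model))
    names(base) <- .ivKinds
    vecs <- base
    if (combinations) {
        norm01 <- lapply(base, function(v) {
            x <- abs(v$values)
            rng <- range(x)
            if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1])
            else rep(0, length(x))
        })
        kinds <- names(base)
        for (i in seq_along(kinds)[-length(kinds)]) {
            for (j in (i + 1L):length(kinds)) {
                nm <- paste(kinds[i], kinds[j], sep = "*")
                vecs[[nm]] <- structure(
                    list(kind = nm,
                         values = norm01[[i]] * norm01[[j]],
                         h = model@nLv),
                    class = "InformativeVector")
            }
        }
    }
    vecs
}
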