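## Shared fixtures: small random spectra and a compact planted-signal
## dataset used across the selection tests.

randomSpectraSet <- function(n = 5, p = 20, seed = 1, withY = TRUE) {
    set.seed(seed)
    SpectraSet(matrix(rnorm(n * p), n), wavelengths = seq_len(p) + 999,
               concentrations = if (withY) runif(n, 0.05, 0.2))
}

## y is an exact (or noisy) linear function of `signal` planted columns;
## the rest are independent noise.
plantedData <- function(n = 60, p = 40, signal = 1:5, noise = 0.05,
                        seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n)
    beta <- numeric(p)
    beta[signal] <- seq(1, 2, length.out = length(signal))
    y <- as.vector(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y, signal = signal, beta = beta)
}

## Small synthetic scenario used where the full default would be slow.
smallScenario <- function(nSamples = 60, nPoints = 120, ...)
    nirScenario(nSamples = nSamples, nPoints = nPoints, ...)
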