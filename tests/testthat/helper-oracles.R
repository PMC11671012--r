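# Independent oracles and fixture builders shared across tests.

STUDY_TIMEPOINTS <- c(0, 0.25, 1, 4, 16, 32)

# noise-free or noisy labeling curve for one peptide
makeTimeCourse <- function(k, t = STUDY_TIMEPOINTS, noise_sd = 0) {
    y <- 1 - exp(-k * t)
    if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
    list(time_days = t, fraction_new = y)
}

# exhaustive grid-search minimizer of the same SSE the fitter minimizes
gridSearchRate <- function(t, y, lo = 1e-4, hi = 10, step = 1e-4) {
    ks <- seq(lo, hi, by = step)
    E <- exp(outer(ks, t, function(k, tt) -k * tt))
    sse <- rowSums((1 - E - rep(y, each = length(ks)))^2)
    ks[which.min(sse)]
}

# brute-force step-up Benjamini-Hochberg from the definition
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
        js <- seq(i, m)
        q[o[i]] <- min(1, min(p[o[js]] * m / js))
    }
    q
}

# independent two-pass standardizations
twoPassAutoScale <- function(x) {
    mu <- sum(x) / length(x)
    s <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    (x - mu) / s
}
twoPassRangeScale <- function(x) {
    mu <- sum(x) / length(x)
    (x - mu) / (max(x) - min(x))
}

# a centered-stage AbundanceExperiment from an explicit matrix
centeredExperiment <- function(values, genotypes) {
    values <- sweep(values, 2L, colMeans(values, na.rm = TRUE))
    AbundanceExperiment(values, data.frame(genotype = genotypes),
                        stage = "centered")
}

# small all-noise-off configuration for exact end-to-end checks
noiseFreeConfig <- function(n_proteins, seed, ...) {
    simulationConfig(
        n_proteins = n_proteins, seed = seed,
        abundance_noise_sd = 0, fraction_new_noise_sd = 0,
        missing_rate = 0, sample_offset_sd = 0, dataset_offset_sd = 0,
        sample_width_sd = 0, ...)
}
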