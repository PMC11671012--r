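## Label-free quantification chain, applied independently per dataset:
## missingness filter -> log2 + per-sample mean centering -> per-sample
## slope normalization against the mean profile -> KNN imputation ->
## variance-test-gated differential t-tests. Fold changes are then averaged
## across datasets and range scaled per comparison.

#' Filter proteins by per-genotype missingness
#'
#' Retains proteins with at most \code{max_missing} missing Area values
#' within each genotype's sample group of the dataset; a protein failing the
#' rule in any genotype is dropped. The number of dropped proteins is stored
#' in \code{metadata(.)$n_filtered_missing}.
#'
#' @param object an \linkS4class{AbundanceExperiment} at stage \code{"raw"}.
#' @param max_missing maximum missing values allowed per genotype
#'   (default 1).
#' @return the filtered object, still at stage \code{"raw"}.
#' @export
filterMissingness <- function(object, max_missing = 1L) {
    stopifnot(is(object, "AbundanceExperiment"))
    if (object@stage != "raw") stop("missingness filter applies to raw areas")
    v <- assay(object)
    geno <- as.character(colData(object)$genotype)
    keep <- rep(TRUE, nrow(v))
    for (g in unique(geno)) {
        nmiss <- rowSums(is.na(v[, geno == g, drop = FALSE]))
        keep <- keep & nmiss <= max_missing
    }
    out <- object[keep, ]
    metadata(out)$n_filtered_missing <- sum(!keep)
    if (!any(keep)) warning("missingness filter removed every protein")
    out
}

#' Log2 transform and per-sample mean centering
#'
#' Takes log2 of all present Area values and subtracts, within each sample,
#' the sample's mean over its present values. Centering removes per-sample
#' multiplicative factors (loading, injection amount); missing values are
#' ignored in the mean and stay missing.
#'
#' @param object an \linkS4class{AbundanceExperiment} at stage \code{"raw"}.
#' @return the object at stage \code{"centered"}.
#' @export
log2AndCenter <- function(object) {
    stopifnot(is(object, "AbundanceExperiment"))
    if (object@stage != "raw") stop("log2 transform applies to raw areas")
    v <- assay(object)
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        stop("non-positive area for protein ", rownames(v)[bad[1, 1]],
             " in sample ", colnames(v)[bad[1, 2]])
    }
    lv <- log2(v)
    lv <- sweep(lv, 2L, colMeans(lv, na.rm = TRUE))
    assay(object) <- lv
    .advanceStage(object, from = "raw", to = "centered")
}

#' Per-sample slope normalization against the mean profile
#'
#' Equalizes distribution widths across samples. The reference profile is
#' the across-sample mean of each protein's centered values; for each
#' sample the least-squares slope through the origin of the sample's values
#' on the reference (over the proteins present in that sample) is computed,
#' and the sample's values are divided by it.
#'
#' @param object an \linkS4class{AbundanceExperiment} at stage
#'   \code{"centered"}.
#' @param min_slope magnitude below which a sample slope is considered
#'   degenerate (error).
#' @return the object at stage \code{"slope_normalized"}; the slopes are
#'   stored in \code{metadata(.)$sample_slopes}.
#' @export
slopeNormalize <- function(object, min_slope = 1e-6) {
    stopifnot(is(object, "AbundanceExperiment"))
    if (object@stage != "centered") {
        stop("slope normalization applies to centered values")
    }
    v <- assay(object)
    r <- rowMeans(v, na.rm = TRUE)
    slopes <- vapply(seq_len(ncol(v)), function(j) {
        p <- !is.na(v[, j]) & !is.na(r)
        sum(r[p] * v[p, j]) / sum(r[p]^2)
    }, numeric(1))
    if (any(!is.finite(slopes)) || any(abs(slopes) < min_slope)) {
        stop("degenerate sample slope in sample ",
             colnames(v)[which(!is.finite(slopes) |
                               abs(slopes) < min_slope)[1]])
    }
    assay(object) <- sweep(v, 2L, slopes, `/`)
    names(slopes) <- colnames(v)
    metadata(object)$sample_slopes <- slopes
    .advanceStage(object, from = "centered", to = "slope_normalized")
}

## nan-aware Euclidean distances from row i to all rows of V: squared
## differences over mutually present columns, rescaled by the inverse
## proportion of shared columns (so sparsely shared rows are not favoured).
.nanEuclidean <- function(V, i) {
    d2 <- sweep(V, 2L, V[i, ])^2
    shared <- rowSums(!is.na(d2))
    ss <- rowSums(d2, na.rm = TRUE)
    d <- sqrt(ss * ncol(V) / shared)
    d[shared == 0L] <- Inf
    d
}

#' K-nearest-neighbour imputation of missing values
#'
#' Fills each missing cell with the mean of the values, in the same sample,
#' of the \code{k} nearest neighbour proteins. Nearness is nan-aware
#' Euclidean distance across samples (squared differences over mutually
#' present samples, rescaled by the proportion shared); only neighbours
#' with the target sample present are eligible. With fewer than \code{k}
#' eligible neighbours the available ones are used; with none, the sample
#' mean is used and a warning issued. Present values are never altered.
#'
#' @param object an \linkS4class{AbundanceExperiment} at stage
#'   \code{"slope_normalized"}.
#' @param k neighbour count (default 2).
#' @return the object at stage \code{"imputed"}; the pre-imputation
#'   presence mask is kept in \code{metadata(.)$observed}.
#' @export
knnImpute <- function(object, k = 2L) {
    stopifnot(is(object, "AbundanceExperiment"), k >= 1L)
    if (object@stage != "slope_normalized") {
        stop("imputation applies to slope-normalized values")
    }
    v <- assay(object)
    metadata(object)$observed <- !is.na(v)
    rows_missing <- which(rowSums(is.na(v)) > 0L)
    filled <- v
    for (i in rows_missing) {
        d <- .nanEuclidean(v, i)
        d[i] <- Inf
        ord <- order(d)
        for (j in which(is.na(v[i, ]))) {
            cand <- ord[!is.na(v[ord, j]) & is.finite(d[ord])]
            if (length(cand) == 0L) {
                warning("no eligible neighbour for ", rownames(v)[i],
                        " in sample ", colnames(v)[j],
                        "; using the sample mean")
                filled[i, j] <- mean(v[, j], na.rm = TRUE)
            } else {
                use <- cand[seq_len(min(k, length(cand)))]
                filled[i, j] <- mean(v[use, j])
            }
        }
    }
    assay(object) <- filled
    .advanceStage(object, from = "slope_normalized", to = "imputed")
}

.rowVars <- function(X) {
    n <- ncol(X)
    m <- rowMeans(X)
    rowSums((X - m)^2) / (n - 1L)
}

#' Variance-test-gated differential abundance tests
#'
#' Per protein, a two-sided F-test compares the group variances at
#' \code{f_alpha}; proteins with an insignificant F-test get a two-sample
#' homoscedastic (pooled-variance) t-test and proteins with a significant
#' F-test a heteroscedastic (Welch) t-test. The fold change is the
#' difference of group means on the normalized log2 scale. Computation is
#' vectorized over proteins from the textbook formulas.
#'
#' @param object an \linkS4class{AbundanceExperiment} at stage
#'   \code{"imputed"}.
#' @param exp_genotype,ctrl_genotype genotype labels of the experimental
#'   and control groups (e.g. \code{"E2"}, \code{"E3"}).
#' @param f_alpha significance level of the variance gate (default 0.05).
#' @return data.frame with \code{protein_id}, \code{dataset_id},
#'   \code{log2_fc}, \code{p_value}, \code{f_test_p}, \code{test_used},
#'   \code{n_exp}, \code{n_ctrl} and the pre-imputation observation counts
#'   \code{n_obs_exp}, \code{n_obs_ctrl}.
#' @export
differentialTest <- function(object, exp_genotype, ctrl_genotype,
                             f_alpha = 0.05) {
    stopifnot(is(object, "AbundanceExperiment"))
    if (object@stage != "imputed") {
        stop("differential testing applies to the imputed stage")
    }
    v <- assay(object)
    geno <- as.character(colData(object)$genotype)
    X1 <- v[, geno == exp_genotype, drop = FALSE]
    X2 <- v[, geno == ctrl_genotype, drop = FALSE]
    n1 <- ncol(X1)
    n2 <- ncol(X2)
    if (n1 < 2L || n2 < 2L) {
        warning("fewer than 2 samples in a group; no test performed")
        return(data.frame(protein_id = character(0)))
    }
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- .rowVars(X1); v2 <- .rowVars(X2)
    Fstat <- v1 / v2
    f_p <- 2 * pmin(stats::pf(Fstat, n1 - 1L, n2 - 1L),
                    stats::pf(Fstat, n1 - 1L, n2 - 1L, lower.tail = FALSE))
    f_p <- pmin(f_p, 1)
    # variance gate is undecidable when both variances are 0; treat as equal
    f_p[v1 == 0 & v2 == 0] <- 1
    welch <- f_p < f_alpha
    se2 <- ifelse(welch,
        v1 / n1 + v2 / n2,
        ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L) * (1 / n1 + 1 / n2))
    df <- ifelse(welch,
        (v1 / n1 + v2 / n2)^2 /
            ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L)),
        n1 + n2 - 2L)
    delta <- m1 - m2
    tstat <- delta / sqrt(se2)
    tstat[se2 == 0 & delta == 0] <- 0
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    p[se2 == 0 & delta == 0] <- 1
    p[se2 == 0 & delta != 0] <- 0
    obs <- metadata(object)$observed
    if (is.null(obs)) obs <- !is.na(v)
    data.frame(
        protein_id = rownames(v),
        dataset_id = datasetId(object),
        log2_fc = delta,
        p_value = p,
        f_test_p = f_p,
        test_used = ifelse(welch, "heteroscedastic", "homoscedastic"),
        n_exp = n1, n_ctrl = n2,
        n_obs_exp = rowSums(obs[, geno == exp_genotype, drop = FALSE]),
        n_obs_ctrl = rowSums(obs[, geno == ctrl_genotype, drop = FALSE]),
        row.names = NULL, stringsAsFactors = FALSE
    )
}

#' Average fold changes across datasets
#'
#' Pools per-dataset differential results for one comparison and averages
#' each protein's log2 fold change over the datasets in which it was
#' quantified with at least \code{min_measurements} observed (pre-imputation)
#' values in both the experimental and the control group. Proteins passing
#' in no dataset are excluded and counted in the \code{"n_excluded"}
#' attribute.
#'
#' @param results data.frame of per-dataset differential results (rows from
#'   [differentialTest()], possibly several datasets row-bound), or a list
#'   of such data.frames.
#' @param min_measurements minimum observed values per group per dataset
#'   (default 3).
#' @return data.frame with \code{protein_id}, \code{mean_log2_fc},
#'   \code{n_datasets}, ordered by protein. Apply [rangeScale()] to
#'   \code{mean_log2_fc} across the comparison to obtain \code{scaled_fc}.
#' @export
averageFC <- function(results, min_measurements = 3L) {
    if (is.list(results) && !is.data.frame(results)) {
        results <- do.call(rbind, results)
    }
    all_proteins <- unique(results$protein_id)
    ok <- results$n_obs_exp >= min_measurements &
        results$n_obs_ctrl >= min_measurements
    results <- results[ok, , drop = FALSE]
    s <- split(results$log2_fc, results$protein_id)
    out <- data.frame(
        protein_id = names(s),
        mean_log2_fc = vapply(s, mean, numeric(1)),
        n_datasets = lengths(s),
        row.names = NULL, stringsAsFactors = FALSE
    )
    out <- out[order(out$protein_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_excluded") <- length(setdiff(all_proteins, out$protein_id))
    out
}

#' Range scaling
#'
#' \code{(x - mean(x)) / (max(x) - min(x))}: centers a fold-change vector
#' and rescales it to unit span, so ontology means computed from it reflect
#' relative change within the comparison's full dynamic range. The scaled
#' vector has mean 0 and span (max - min) 1.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return scaled numeric vector.
#' @examples
#' rangeScale(c(1, 2, 3)) # -0.5 0 0.5
#' @export
rangeScale <- function(values) {
    if (length(values) < 2L) stop("range scaling requires at least 2 values")
    span <- max(values) - min(values)
    if (!is.finite(span) || span == 0) {
        stop("degenerate input: zero range, range scaling undefined")
    }
    (values - mean(values)) / span
}
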