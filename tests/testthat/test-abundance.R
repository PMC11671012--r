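makeRawExperiment <- function(values, genotypes) {
    AbundanceExperiment(values, data.frame(genotype = genotypes),
                        dataset_id = "test")
}

test_that("missingness filter applies the n-1 rule per genotype", {
    geno <- rep(c("E2", "E3", "E4"), each = 4)
    m <- matrix(100, 3, 12,
                dimnames = list(c("full", "two_gone", "one_each"), NULL))
    m["two_gone", c(1, 2)] <- NA       # 2 of 4 E2 samples missing
    m["one_each", c(1, 5, 9)] <- NA    # exactly 1 missing per genotype
    ae <- filterMissingness(makeRawExperiment(m, geno))
    expect_setequal(rownames(ae), c("full", "one_each"))
    expect_identical(S4Vectors::metadata(ae)$n_filtered_missing, 1L)
    expect_error(filterMissingness(log2AndCenter(
        makeRawExperiment(matrix(2, 2, 12), geno))), "raw")
})

test_that("log2 transform and centering remove per-sample scale", {
    m <- matrix(c(2, 8, 4, 16), 2, 2)
    ae <- log2AndCenter(makeRawExperiment(m, c("E2", "E3")))
    expect_equal(unname(SummarizedExperiment::assay(ae)),
                 matrix(c(-1, 1, -1, 1), 2, 2))
    expect_identical(abundanceStage(ae), "centered")

    # columns identical up to a multiplicative constant center identically
    m2 <- cbind(s1 = c(3, 7, 20), s2 = 5.7 * c(3, 7, 20))
    ae2 <- log2AndCenter(makeRawExperiment(m2, c("E2", "E3")))
    v <- SummarizedExperiment::assay(ae2)
    expect_equal(v[, 1], v[, 2], tolerance = 1e-12, ignore_attr = TRUE)

    # missing values are ignored in the sample mean
    m3 <- matrix(c(4, NA, 16), 3, 1)
    v3 <- SummarizedExperiment::assay(log2AndCenter(
        makeRawExperiment(m3, "E2")))
    expect_equal(unname(v3[, 1]), c(-1, NA, 1))

    bad <- matrix(c(2, 0, 4, 8), 2, 2,
                  dimnames = list(c("pA", "pB"), c("s1", "s2")))
    expect_error(log2AndCenter(makeRawExperiment(bad, c("E2", "E3"))),
                 "pB.*s1")
})

test_that("slope normalization rescales each sample onto the mean profile", {
    r <- c(-2, -1, 0, 1, 2)
    # one sample on the reference, one at twice its width
    v <- cbind(a = r, b = 2 * r, c = r)
    ae <- slopeNormalize(centeredExperiment(v, c("E2", "E3", "E3")))
    out <- SummarizedExperiment::assay(ae)
    ref <- rowMeans(cbind(r, 2 * r, r))
    sl <- S4Vectors::metadata(ae)$sample_slopes
    expect_equal(unname(sl), c(1, 2, 1) * sum(ref * r) / sum(ref^2))
    expect_equal(out[, "a"], out[, "b"], tolerance = 1e-12,
                 ignore_attr = TRUE)

    # slopes match an independent no-intercept OLS fit
    set.seed(33)
    m <- matrix(rnorm(300), 50, 6)
    m <- sweep(m, 2, colMeans(m))
    ae2 <- slopeNormalize(centeredExperiment(m, rep(c("E2", "E3"), 3)))
    v2 <- sweep(m, 2, colMeans(m)) # construction already centered
    rr <- rowMeans(v2)
    b_oracle <- vapply(seq_len(6), function(j) {
        unname(coef(lm(v2[, j] ~ rr + 0)))
    }, numeric(1))
    expect_equal(unname(S4Vectors::metadata(ae2)$sample_slopes), b_oracle,
                 tolerance = 1e-10)

    degenerate <- centeredExperiment(cbind(c(-1, 0, 1), c(1, 0, -1)),
                                     c("E2", "E3"))
    expect_error(slopeNormalize(degenerate), "degenerate")
})

test_that("KNN imputation fills from nearest neighbours and nothing else", {
    base <- c(-2, -1, 0, 1, 2, 0)
    v <- rbind(target = base, twinA = base + 1e-3, twinB = base - 1e-3,
               far = rev(base) * 4)
    v["target", 3] <- NA
    v <- sweep(v, 2, colMeans(v, na.rm = TRUE))
    ae <- AbundanceExperiment(v, data.frame(genotype = rep(c("E2", "E3"),
                                                           each = 3)),
                              stage = "slope_normalized")
    imp <- knnImpute(ae, k = 2)
    out <- SummarizedExperiment::assay(imp)
    expect_equal(out["target", 3], mean(v[c("twinA", "twinB"), 3]))
    # conservatism: present values untouched
    expect_identical(out[!is.na(v)], v[!is.na(v)])
    expect_identical(abundanceStage(imp), "imputed")
    expect_false(anyNA(out))

    # an exact duplicate row is copied verbatim with k = 1
    v2 <- rbind(a = base, dup = base)
    v2["a", 2] <- NA
    v2 <- sweep(v2, 2, colMeans(v2, na.rm = TRUE))
    ae2 <- AbundanceExperiment(v2, data.frame(genotype = rep("E2", 6)),
                               stage = "slope_normalized")
    out2 <- SummarizedExperiment::assay(knnImpute(ae2, k = 1))
    expect_equal(out2["a", 2], out2["dup", 2])

    # a complete matrix passes through unchanged
    full <- matrix(rnorm(24), 4, 6)
    full <- sweep(full, 2, colMeans(full))
    ae3 <- AbundanceExperiment(full, data.frame(genotype = rep("E2", 6)),
                               stage = "slope_normalized")
    expect_identical(SummarizedExperiment::assay(knnImpute(ae3)),
                     SummarizedExperiment::assay(ae3))
})

test_that("differential tests gate on the F-test and match stats oracles", {
    set.seed(44)
    n <- 40
    X <- matrix(rnorm(n * 8), n, 8)
    X[1, 1:4] <- c(1, 2, 3, 2); X[1, 5:8] <- c(1, 2, 3, 2) # identical groups
    X[2, 5:8] <- X[2, 5:8] * 10 # variance ratio 100
    geno <- rep(c("E2", "E3"), each = 4)
    ae <- AbundanceExperiment(X, data.frame(genotype = geno),
                              stage = "imputed", dataset_id = "d1")
    res <- differentialTest(ae, "E2", "E3")

    expect_equal(res$log2_fc[1], 0)
    expect_equal(res$p_value[1], 1)
    expect_identical(res$test_used[2], "heteroscedastic")
    expect_identical(res$test_used == "heteroscedastic",
                     res$f_test_p < 0.05)

    for (i in c(2, 5, 17, 30)) {
        x1 <- X[i, geno == "E2"]; x2 <- X[i, geno == "E3"]
        vt <- var.test(x1, x2)
        expect_equal(res$f_test_p[i], vt$p.value, tolerance = 1e-10)
        tt <- t.test(x1, x2, var.equal = vt$p.value >= 0.05)
        expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
        expect_equal(res$log2_fc[i], mean(x1) - mean(x2), tolerance = 1e-12)
    }
})

test_that("null data yield a uniform-rate of nominal false positives", {
    set.seed(55)
    n <- 1000
    X <- matrix(rnorm(n * 8), n, 8)
    ae <- AbundanceExperiment(X, data.frame(genotype = rep(c("E2", "E3"),
                                                           each = 4)),
                              stage = "imputed")
    res <- differentialTest(ae, "E2", "E3")
    frac <- mean(res$p_value < 0.05)
    ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
    expect_gte(frac, ci[1])
    expect_lte(frac, ci[2])
})

test_that("fold changes average across datasets with the measurement floor", {
    base <- data.frame(protein_id = "A", dataset_id = "d1", log2_fc = 1,
                       p_value = 0.5, f_test_p = 0.5,
                       test_used = "homoscedastic", n_exp = 4, n_ctrl = 4,
                       n_obs_exp = 4L, n_obs_ctrl = 4L)
    d2 <- transform(base, dataset_id = "d2", log2_fc = 0.5)
    avg <- averageFC(rbind(base, d2))
    expect_equal(avg$mean_log2_fc, 0.75)
    expect_identical(avg$n_datasets, 2L)

    # a single qualifying dataset passes its value through
    single <- averageFC(base)
    expect_equal(single$mean_log2_fc, 1)

    # two observed control measurements never qualify
    starved <- transform(base, n_obs_ctrl = 2L)
    out <- averageFC(rbind(starved, transform(starved, dataset_id = "d2")))
    expect_identical(nrow(out), 0L)
    expect_identical(attr(out, "n_excluded"), 1L)
})

test_that("range scaling centers to mean 0 and unit span", {
    expect_equal(rangeScale(c(1, 2, 3)), c(-0.5, 0, 0.5))
    expect_equal(rangeScale(c(0, 10)), c(-0.5, 0.5))
    expect_error(rangeScale(c(2, 2)), "degenerate")
    set.seed(66)
    x <- runif(1000)
    sc <- rangeScale(x)
    expect_lt(abs(mean(sc)), 1e-12)
    expect_lt(abs(diff(range(sc)) - 1), 1e-12)
    expect_equal(sc, twoPassRangeScale(x), tolerance = 1e-12)
    # invariance under positive affine transforms of the input
    expect_equal(rangeScale(3.2 * x + 7), rangeScale(x), tolerance = 1e-12)
})

test_that("the stage machine only moves forward", {
    m <- matrix(c(2, 8, 4, 16), 2, 2)
    ae <- makeRawExperiment(m, c("E2", "E3"))
    ae <- log2AndCenter(ae)
    expect_error(log2AndCenter(ae), "raw")
    ae <- slopeNormalize(ae)
    expect_error(slopeNormalize(ae), "centered")
    ae <- knnImpute(ae)
    expect_error(knnImpute(ae), "slope-normalized")
    expect_error(differentialTest(makeRawExperiment(m, c("E2", "E3")),
                                  "E2", "E3"), "imputed")
})
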