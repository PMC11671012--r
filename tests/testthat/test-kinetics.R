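test_that("steady state and labeling closed forms obey the model", {
    expect_equal(steadyStateAbundance(10, 2), 5)
    expect_equal(steadyStateAbundance(3, 0.5), 6)
    expect_equal(steadyStateAbundance(0.7, 0.7), 1)
    expect_error(steadyStateAbundance(-1, 2), "invalid")
    expect_error(steadyStateAbundance(1, 0), "invalid")

    expect_equal(labelingCurves(5, 1.3, 0)$fraction_new, 0)
    expect_equal(labelingCurves(1, log(2), 1)$fraction_new, 0.5)
    lc <- labelingCurves(10, 2, 5)
    expect_identical(lc$unlabeled + lc$labeled, 5)
    expect_error(labelingCurves(1, 1, -0.1), "non-negative")
})

test_that("labeled + unlabeled pools conserve the steady state at all times", {
    set.seed(11)
    tgrid <- seq(0, 64, length.out = 65)
    for (i in 1:25) {
        ksyn <- exp(runif(1, log(0.1), log(100)))
        kdeg <- exp(runif(1, log(0.01), log(2)))
        lc <- labelingCurves(ksyn, kdeg, tgrid)
        expect_lt(max(abs(lc$unlabeled + lc$labeled - ksyn / kdeg)), 1e-12)
        # fraction new rises monotonically towards 1 (strictly, until it
        # saturates at 1 in double precision)
        expect_true(all(diff(lc$fraction_new) >= 0))
        unsat <- lc$fraction_new < 1 - 1e-12
        expect_true(all(diff(lc$fraction_new[unsat]) > 0))
        expect_lt(abs(1 - labelingCurves(ksyn, kdeg, 5000)$fraction_new),
                  1e-12)
    }
    # fraction new increases with the degradation rate at fixed time
    f <- vapply(c(0.05, 0.1, 0.5, 1), function(k) {
        labelingCurves(1, k, 2)$fraction_new
    }, numeric(1))
    expect_true(all(diff(f) > 0))
})

test_that("turnover rate is the mean of per-molar synthesis and degradation", {
    expect_equal(turnoverRate(10, P = 5, kdeg = 2), 2) # homeostasis
    expect_equal(turnoverRate(10, P = 10, kdeg = 2), 1.5)
    expect_equal(turnoverRate(0, P = 1, kdeg = 0.8), 0.4)
    expect_error(turnoverRate(1, P = 0, kdeg = 1), "P > 0")
})

test_that("peptide rate fitting recovers noise-free rates exactly", {
    for (k in c(0.02, 0.2, 1.5)) {
        tc <- makeTimeCourse(k)
        fit <- fitPeptideRate(tc$time_days, tc$fraction_new)
        expect_true(fit$accepted)
        expect_lt(abs(fit$k - k) / k, 1e-6)
        expect_gte(fit$rsq, 0.999999)
        expect_lt(fit$deviation, 1e-7)
    }
})

test_that("peptide fits are rejected for the stated reasons", {
    # two distinct non-zero timepoints: below the three-timepoint minimum
    fit <- fitPeptideRate(c(0, 1, 4), 1 - exp(-0.3 * c(0, 1, 4)))
    expect_false(fit$accepted)
    expect_identical(fit$reason, "min-timepoints")
    # replicates at the same non-zero time do not add distinct timepoints
    fit2 <- fitPeptideRate(c(0, 1, 1, 4, 4), rep(0.4, 5))
    expect_identical(fit2$reason, "min-timepoints")
    # an all-zero labeling signal pins the rate at the lower bound
    fit3 <- fitPeptideRate(STUDY_TIMEPOINTS, rep(0, 6))
    expect_false(fit3$accepted)
    expect_identical(fit3$reason, "non-converged")
    # gross scatter fails the RMS-deviation gate
    set.seed(5)
    y <- 1 - exp(-0.3 * STUDY_TIMEPOINTS) + rnorm(6, 0, 0.4)
    fit4 <- fitPeptideRate(STUDY_TIMEPOINTS, y)
    expect_identical(fit4$reason, "deviation")
    expect_error(fitPeptideRate(c(-1, 2, 3), c(0, 0.1, 0.2)), "negative")
})

test_that("fitted rates agree with an exhaustive grid-search oracle", {
    set.seed(91)
    for (i in 1:12) {
        k <- exp(runif(1, log(0.05), log(2)))
        tc <- makeTimeCourse(k, noise_sd = 0.05)
        fit <- fitPeptideRate(tc$time_days, tc$fraction_new,
                              max_deviation = Inf)
        k_grid <- gridSearchRate(tc$time_days, tc$fraction_new)
        expect_lt(abs(fit$k - k_grid), 1e-3)
    }
})

test_that("protein-level combination is the median with pooled diagnostics", {
    t6 <- STUDY_TIMEPOINTS
    one <- combineProteinRate(0.3, t6, 1 - exp(-0.3 * t6), "pepA", "P1")
    expect_equal(one$rate_per_day, 0.3)
    expect_identical(one$n_unique_peptides, 1L)
    expect_identical(one$asymptote, 1)

    med <- combineProteinRate(c(0.1, 0.2, 0.9),
                              rep(t6, 3),
                              1 - exp(-0.2 * rep(t6, 3)),
                              rep(c("a", "b", "c"), each = 6))
    expect_equal(med$rate_per_day, 0.2)

    # two noise-free peptides from the same true rate: pooled fit is exact
    y <- 1 - exp(-0.4 * rep(t6, 2))
    two <- combineProteinRate(c(0.4, 0.4), rep(t6, 2), y,
                              rep(c("a", "b"), each = 6))
    res <- (1 - exp(-two$rate_per_day * rep(t6, 2))) - y
    rsq_direct <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_gte(two$rsq, 0.999999)
    expect_equal(two$rsq, rsq_direct)
    expect_error(combineProteinRate(numeric(0), 1, 1, "a"), "no accepted")
})

test_that("fitProteinRates pools peptides and counts rejections", {
    t6 <- STUDY_TIMEPOINTS
    tc <- rbind(
        data.frame(protein_id = "P1", peptide_id = "p1", time_days = t6,
                   fraction_new = 1 - exp(-0.2 * t6)),
        data.frame(protein_id = "P1", peptide_id = "p2", time_days = t6,
                   fraction_new = 1 - exp(-0.25 * t6)),
        data.frame(protein_id = "P2", peptide_id = "p3",
                   time_days = c(0, 1, 4),
                   fraction_new = 1 - exp(-0.5 * c(0, 1, 4))))
    fits <- fitProteinRates(tc)
    expect_identical(fits$protein_id, "P1")
    expect_equal(fits$rate_per_day, median(c(0.2, 0.25)), tolerance = 1e-6)
    expect_identical(fits$n_unique_peptides, 2L)
    expect_identical(attr(fits, "peptide_rejections")[["min-timepoints"]], 1L)
    expect_identical(attr(fits, "n_proteins_dropped"), 1L)
})

test_that("optional n-value gate removes low-labeling-capacity peptides", {
    t6 <- STUDY_TIMEPOINTS
    tc <- rbind(
        data.frame(protein_id = "P1", peptide_id = "p1", time_days = t6,
                   fraction_new = 1 - exp(-0.2 * t6), n_value = 4L),
        data.frame(protein_id = "P1", peptide_id = "p2", time_days = t6,
                   fraction_new = 1 - exp(-0.8 * t6), n_value = 12L))
    default <- fitProteinRates(tc)
    gated <- fitProteinRates(tc, min_n_value = 5)
    expect_equal(default$rate_per_day, median(c(0.2, 0.8)), tolerance = 1e-5)
    expect_equal(gated$rate_per_day, 0.8, tolerance = 1e-5)
})

test_that("rate QC filter keeps exactly the valid fits and partitions the rest", {
    fits <- data.frame(
        protein_id = c("A", "B", "C", "D"),
        rate_per_day = c(0.2, 0.2, 0, 0.3),
        rsq = c(0.55, 0.9, 0.9, 0.8),
        n_unique_peptides = c(3L, 1L, 3L, 2L))
    fl <- filterRateFits(fits)
    expect_identical(fl$accepted$protein_id, "D")
    expect_identical(
        fl$rejected$rejection_reason[match(c("A", "B", "C"),
                                           fl$rejected$protein_id)],
        c("rsq", "unique-peptides", "rate-positivity"))
    expect_identical(unname(fl$counts), c(1L, 1L, 1L))
    # accepted + rejected partition the input; filtering is idempotent
    expect_identical(nrow(fl$accepted) + sum(fl$counts), nrow(fits))
    again <- filterRateFits(fl$accepted)
    expect_identical(again$accepted, fl$accepted)
    expect_identical(sum(again$counts), 0L)
})

test_that("turnover fold changes are log2 differences of cohort mean rates", {
    e <- data.frame(protein_id = c("A", "B", "C"),
                    rate_per_day = c(0.2, 0.3, 0.05))
    c0 <- data.frame(protein_id = c("A", "B", "C", "D"),
                     rate_per_day = c(0.1, 0.3, 0.2, 1))
    fc <- computeTurnoverFC(e, c0)
    expect_equal(fc$log2_rate_fc[fc$protein_id == "A"], 1)
    expect_equal(fc$log2_rate_fc[fc$protein_id == "B"], 0)
    expect_equal(fc$log2_rate_fc[fc$protein_id == "C"], -2)
    expect_identical(unname(attr(fc, "n_excluded")["ctrl_only"]), 1L)

    # a protein measured in two datasets is averaged within the cohort first
    e2 <- data.frame(protein_id = c("A", "A"), rate_per_day = c(0.1, 0.3))
    c2 <- data.frame(protein_id = "A", rate_per_day = 0.1)
    fc2 <- computeTurnoverFC(e2, c2)
    expect_equal(fc2$log2_rate_fc, 1)
    expect_identical(fc2$n_datasets_exp, 2L)
    expect_error(computeTurnoverFC(
        data.frame(protein_id = "A", rate_per_day = -1), c2), "non-positive")
})

test_that("auto scaling standardizes to mean 0 and unit sample sd", {
    expect_equal(autoScale(c(1, 2, 3)), c(-1, 0, 1))
    expect_error(autoScale(c(5, 5, 5)), "degenerate")
    expect_error(autoScale(3), "at least 2")
    set.seed(21)
    x <- rnorm(1000)
    sc <- autoScale(x)
    expect_lt(abs(mean(sc)), 1e-12)
    expect_lt(abs(sd(sc) - 1), 1e-12)
    expect_equal(sc, twoPassAutoScale(x), tolerance = 1e-12)
    # idempotence: scaling a scaled vector changes nothing
    expect_equal(autoScale(sc), sc, tolerance = 1e-12)
})
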