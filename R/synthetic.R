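## Synthetic-data generator emulating the study design the pipeline expects:
## three genotypes (E2/E3/E4, E3 the control), eight LFQ datasets crossing
## sex x block x subcellular fraction with four samples per genotype each,
## and D2O labeling time courses at 0, 0.25, 1, 4, 16 and 32 days. Every
## quantity derives from per-protein (ksyn, kdeeg) ground truth so pipeline
## output can be checked against construction.

.REGULATION_CLASSES <- c("synthesis_up", "synthesis_down",
                         "degradation_up", "degradation_down")

#' Simulation configuration
#'
#' Collects the study-design constants and noise levels for the generator.
#' Defaults emulate the design the analysis assumes: genotypes E2/E3/E4
#' with E3 as control, eight datasets crossing sex (F/M), block (1/2) and
#' subcellular fraction (cytosol/membrane) with 4 samples per genotype
#' each, labeling timepoints 0, 0.25 (6 h), 1, 4, 16 and 32 days, 1-5
#' peptides per protein, log2 abundance noise sd 0.25, fraction-new noise
#' sd 0.03, 5% missing areas.
#'
#' @param n_proteins number of simulated proteins.
#' @param seed mandatory integer seed; every generator call derives its
#'   stream from it.
#' @param genotypes genotype labels; the first element of
#'   \code{comparisons} names use these.
#' @param control control genotype (reference of every comparison).
#' @param n_samples samples per genotype per dataset.
#' @param timepoints_days labeling timepoints in days.
#' @param n_peptides_range inclusive range peptides-per-protein are drawn
#'   from (uniformly).
#' @param class_fractions named fractions of proteins assigned to each
#'   regulation class per comparison (remainder unregulated); must sum
#'   to <= 1.
#' @param effect_size_log2 log2 effect size applied to a regulated
#'   protein's abundance (synthesis classes) or degradation rate
#'   (degradation classes).
#' @param abundance_noise_sd sd of log2-scale measurement noise on areas.
#' @param fraction_new_noise_sd sd of additive noise on fraction-new values.
#' @param missing_rate Bernoulli rate of missing area cells.
#' @param sample_offset_sd sd of the per-sample additive log2 offset
#'   (between-animal and loading variation).
#' @param dataset_offset_sd sd of the per-dataset additive log2 offset.
#' @param sample_width_sd sd (log2) of the per-sample multiplicative
#'   distribution-width factor; non-zero values make the slope
#'   normalization stage consequential.
#' @param ksyn_range,kdeg_range log-uniform ranges of the control-genotype
#'   synthesis rate (arbitrary concentration units/day) and degradation
#'   rate constant (per day).
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_proteins = 300L,
                             seed,
                             genotypes = c("E2", "E3", "E4"),
                             control = "E3",
                             n_samples = 4L,
                             timepoints_days = c(0, 0.25, 1, 4, 16, 32),
                             n_peptides_range = c(1L, 5L),
                             class_fractions = c(synthesis_up = 0.1,
                                                 synthesis_down = 0.1,
                                                 degradation_up = 0.1,
                                                 degradation_down = 0.1),
                             effect_size_log2 = 1,
                             abundance_noise_sd = 0.25,
                             fraction_new_noise_sd = 0.03,
                             missing_rate = 0.05,
                             sample_offset_sd = 0.1,
                             dataset_offset_sd = 0.2,
                             sample_width_sd = 0.05,
                             ksyn_range = c(1, 1000),
                             kdeg_range = c(0.01, 2)) {
    if (missing(seed)) stop("a seed is mandatory")
    cfg <- list(n_proteins = as.integer(n_proteins), seed = as.integer(seed),
                genotypes = genotypes, control = control,
                n_samples = as.integer(n_samples),
                timepoints_days = timepoints_days,
                n_peptides_range = as.integer(n_peptides_range),
                class_fractions = class_fractions,
                effect_size_log2 = effect_size_log2,
                abundance_noise_sd = abundance_noise_sd,
                fraction_new_noise_sd = fraction_new_noise_sd,
                missing_rate = missing_rate,
                sample_offset_sd = sample_offset_sd,
                dataset_offset_sd = dataset_offset_sd,
                sample_width_sd = sample_width_sd,
                ksyn_range = ksyn_range, kdeg_range = kdeg_range)
    stopifnot(cfg$n_proteins >= 1L, cfg$control %in% cfg$genotypes,
              all(cfg$timepoints_days >= 0),
              cfg$n_peptides_range[1] >= 1L,
              all(c(cfg$abundance_noise_sd, cfg$fraction_new_noise_sd,
                    cfg$missing_rate, cfg$sample_offset_sd,
                    cfg$dataset_offset_sd, cfg$sample_width_sd) >= 0))
    if (!all(names(cfg$class_fractions) %in% .REGULATION_CLASSES) ||
        any(cfg$class_fractions < 0) || sum(cfg$class_fractions) > 1) {
        stop("class_fractions must be named by regulation class, ",
             "non-negative and sum to at most 1")
    }
    class(cfg) <- "SimulationConfig"
    cfg
}

## per-stage derived seed, kept below 2^31
.derivedSeed <- function(config, stage) {
    (abs(config$seed) %% 200000000L) * 10L + stage
}

.logUniform <- function(n, range) {
    exp(stats::runif(n, log(range[1]), log(range[2])))
}

## class -> multiplicative (ksyn, kdeg) factors for log2 effect e.
## Synthesis classes move kdeg by half the effect and ksyn by 1.5x the
## effect so abundance moves by the full effect and turnover co-moves;
## degradation classes move kdeg alone (abundance and turnover counter-move)
.classFactors <- function(class, e) {
    switch(class,
        synthesis_up = c(ksyn = 2^(1.5 * e), kdeg = 2^(0.5 * e)),
        synthesis_down = c(ksyn = 2^(-1.5 * e), kdeg = 2^(-0.5 * e)),
        degradation_up = c(ksyn = 1, kdeg = 2^e),
        degradation_down = c(ksyn = 1, kdeg = 2^(-e)),
        none = c(ksyn = 1, kdeg = 1))
}

#' Simulate per-protein kinetic ground truth
#'
#' Draws control-genotype synthesis and degradation rates log-uniformly,
#' assigns each non-control genotype's proteins to regulation classes in
#' the configured fractions (exact counts, via a seeded permutation), and
#' applies the class's coordinated (ksyn, kdeg) change so that each of the
#' four proteostasis quadrants is realized: synthesis classes move
#' abundance and turnover in the same direction, degradation classes in
#' opposite directions.
#'
#' @param config a [simulationConfig()].
#' @return object of class \code{"GroundTruth"}: list with \code{params}
#'   (data.frame protein_id, genotype, ksyn, kdeg, abundance, turnover),
#'   \code{classes} (data.frame protein_id, comparison, class) and the
#'   \code{config}.
#' @export
simulateGroundTruth <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(.derivedSeed(config, 1L))
    n <- config$n_proteins
    ids <- sprintf("P%05d", seq_len(n))
    ksyn0 <- .logUniform(n, config$ksyn_range)
    kdeg0 <- .logUniform(n, config$kdeg_range)
    exp_genos <- setdiff(config$genotypes, config$control)
    params <- list(data.frame(protein_id = ids, genotype = config$control,
                              ksyn = ksyn0, kdeg = kdeg0,
                              stringsAsFactors = FALSE))
    classes <- list()
    fr <- config$class_fractions
    counts <- round(fr * n)
    for (g in exp_genos) {
        cls <- rep("none", n)
        perm <- sample.int(n)
        pos <- 1L
        for (ci in seq_along(counts)) {
            if (counts[ci] == 0L) next
            cls[perm[pos:(pos + counts[ci] - 1L)]] <- names(counts)[ci]
            pos <- pos + counts[ci]
        }
        fac <- t(vapply(cls, .classFactors, numeric(2),
                        e = config$effect_size_log2))
        params[[g]] <- data.frame(protein_id = ids, genotype = g,
                                  ksyn = ksyn0 * fac[, "ksyn"],
                                  kdeg = kdeg0 * fac[, "kdeg"],
                                  stringsAsFactors = FALSE)
        classes[[g]] <- data.frame(
            protein_id = ids,
            comparison = paste0(g, "vs", config$control),
            class = cls, stringsAsFactors = FALSE)
    }
    params <- do.call(rbind, params)
    params$abundance <- params$ksyn / params$kdeg
    params$turnover <- params$kdeg
    rownames(params) <- NULL
    truth <- list(params = params,
                  classes = do.call(rbind, c(classes,
                                             make.row.names = FALSE)),
                  config = config)
    class(truth) <- "GroundTruth"
    truth
}

#' @export
print.GroundTruth <- function(x, ...) {
    cat("GroundTruth:", x$config$n_proteins, "proteins x",
        length(x$config$genotypes), "genotypes\n")
    print(table(x$classes$comparison, x$classes$class))
    invisible(x)
}

#' Simulate peptide labeling time courses
#'
#' For every protein, genotype, peptide and timepoint, generates a
#' fraction-new value from the closed-form labeling curve
#' \code{1 - exp(-kdeg t)} plus Gaussian noise, truncated to [-0.2, 1.2]
#' (measured values may exceed the nominal [0, 1] range). Peptide counts
#' per protein are drawn uniformly from the configured range and shared
#' across genotypes; each peptide also carries a deuterium-site count
#' (\code{n_value}).
#'
#' @param truth a \code{"GroundTruth"} from [simulateGroundTruth()].
#' @param config the same [simulationConfig()].
#' @return data.frame with \code{protein_id}, \code{peptide_id},
#'   \code{genotype}, \code{time_days}, \code{fraction_new},
#'   \code{n_value}.
#' @export
simulateLabelTimecourses <- function(truth, config = truth$config) {
    stopifnot(inherits(truth, "GroundTruth"))
    set.seed(.derivedSeed(config, 2L))
    ids <- unique(truth$params$protein_id)
    npep <- sample(seq(config$n_peptides_range[1], config$n_peptides_range[2]),
                   length(ids), replace = TRUE)
    pep_protein <- rep(ids, npep)
    pep_id <- unlist(lapply(npep, seq_len))
    pep_name <- paste0(pep_protein, "_pep", pep_id)
    n_value <- sample(6:30, length(pep_name), replace = TRUE)
    tp <- config$timepoints_days
    genos <- config$genotypes
    rows <- expand.grid(pep = seq_along(pep_name), genotype = genos,
                        time_days = tp, stringsAsFactors = FALSE)
    kd <- truth$params$kdeg[match(
        paste(pep_protein[rows$pep], rows$genotype),
        paste(truth$params$protein_id, truth$params$genotype))]
    fn <- 1 - exp(-kd * rows$time_days)
    if (config$fraction_new_noise_sd > 0) {
        fn <- fn + stats::rnorm(length(fn), 0, config$fraction_new_noise_sd)
    }
    fn <- pmin(pmax(fn, -0.2), 1.2)
    out <- data.frame(
        protein_id = pep_protein[rows$pep],
        peptide_id = pep_name[rows$pep],
        genotype = rows$genotype,
        time_days = rows$time_days,
        fraction_new = fn,
        n_value = n_value[rows$pep],
        stringsAsFactors = FALSE
    )
    out <- out[order(out$protein_id, out$peptide_id, out$genotype,
                     out$time_days), ]
    rownames(out) <- NULL
    out
}

#' Simulate the eight label-free abundance datasets
#'
#' Generates one \linkS4class{AbundanceExperiment} per dataset (sex x block
#' x subcellular fraction), with \code{n_samples} samples per genotype. On
#' the log2 scale each area is
#' \code{m_j + w_j * (log2(ksyn/kdeg) + noise)}: \code{m_j} is the sample's
#' additive offset (dataset offset plus per-sample offset, removed by mean
#' centering) and \code{w_j} its multiplicative width factor (corrected by
#' slope normalization). Cells go missing independently at
#' \code{missing_rate}.
#'
#' @inheritParams simulateLabelTimecourses
#' @return named list of eight \code{AbundanceExperiment} objects at stage
#'   \code{"raw"}.
#' @export
simulateAbundanceDatasets <- function(truth, config = truth$config) {
    stopifnot(inherits(truth, "GroundTruth"))
    set.seed(.derivedSeed(config, 3L))
    ids <- unique(truth$params$protein_id)
    n <- length(ids)
    design <- expand.grid(block = c(1L, 2L), sex = c("F", "M"),
                          fraction = c("cytosol", "membrane"),
                          stringsAsFactors = FALSE)
    genos <- config$genotypes
    ns <- config$n_samples
    a <- matrix(NA_real_, n, length(genos), dimnames = list(ids, genos))
    for (g in genos) {
        p <- truth$params[truth$params$genotype == g, ]
        a[, g] <- log2(p$ksyn / p$kdeg)[match(ids, p$protein_id)]
    }
    out <- list()
    for (d in seq_len(nrow(design))) {
        ds_id <- paste0(design$sex[d], design$block[d], "_",
                        design$fraction[d])
        ds_offset <- stats::rnorm(1, 0, config$dataset_offset_sd)
        geno_col <- rep(genos, each = ns)
        nsamp <- length(geno_col)
        m_j <- ds_offset + stats::rnorm(nsamp, 0, config$sample_offset_sd)
        w_j <- 2^stats::rnorm(nsamp, 0, config$sample_width_sd)
        eps <- matrix(stats::rnorm(n * nsamp, 0, config$abundance_noise_sd),
                      n, nsamp)
        lv <- sweep(sweep(a[, geno_col, drop = FALSE] + eps, 2L, w_j, `*`),
                    2L, m_j, `+`)
        areas <- 2^lv
        if (config$missing_rate > 0) {
            areas[stats::runif(length(areas)) < config$missing_rate] <- NA
        }
        colnames(areas) <- paste0(ds_id, "_", geno_col,
                                  rep(seq_len(ns), times = length(genos)))
        sd_df <- data.frame(
            sample_id = colnames(areas), genotype = geno_col,
            sex = design$sex[d], block = design$block[d],
            fraction = design$fraction[d], timepoint_days = NA_real_,
            stringsAsFactors = FALSE)
        out[[ds_id]] <- AbundanceExperiment(areas, sd_df,
                                            dataset_id = ds_id)
    }
    out
}

#' Simulate a functional-enrichment (ontology membership) table
#'
#' Constructs null terms (random protein subsets) and designed terms whose
#' members are drawn from a single regulation class of one comparison, with
#' observed/background counts spanning both sides of the 25% coverage
#' threshold. The output uses the enrichment-table dialect
#' [parseEnrichmentTable()] reads.
#'
#' @inheritParams simulateLabelTimecourses
#' @param n_null_terms number of random-membership terms.
#' @param n_designed_per_class designed terms per regulation class per
#'   comparison.
#' @param term_size_range inclusive range of member counts.
#' @param low_coverage_fraction fraction of null terms forced below the
#'   25% coverage threshold (so the filter is exercised).
#' @return list with \code{terms} (data.frame in the shape of
#'   [parseEnrichmentTable()] output) and \code{term_truth} (data.frame
#'   \code{term_id}, \code{comparison}, \code{true_class}; NA comparison
#'   for null terms).
#' @export
simulateOntologyAnnotations <- function(truth, config = truth$config,
                                        n_null_terms = 30L,
                                        n_designed_per_class = 2L,
                                        term_size_range = c(10L, 20L),
                                        low_coverage_fraction = 0.2) {
    stopifnot(inherits(truth, "GroundTruth"))
    set.seed(.derivedSeed(config, 4L))
    ids <- unique(truth$params$protein_id)
    comparisons <- unique(truth$classes$comparison)
    rows <- list()
    truth_rows <- list()
    add_term <- function(term_id, source, desc, members, coverage) {
        obs <- length(members)
        data.frame(term_id = term_id, source = source, description = desc,
                   observed_count = obs,
                   background_count = max(obs, round(obs / coverage)),
                   coverage = NA_real_, stringsAsFactors = FALSE,
                   row.names = NULL)
    }
    members_list <- list()
    k <- 0L
    for (cmp in comparisons) {
        cls_df <- truth$classes[truth$classes$comparison == cmp, ]
        for (cl in .REGULATION_CLASSES) {
            pool <- cls_df$protein_id[cls_df$class == cl]
            if (length(pool) < 2L) next
            for (r in seq_len(n_designed_per_class)) {
                size <- min(length(pool),
                            sample(seq(term_size_range[1],
                                       term_size_range[2]), 1L))
                mem <- sample(pool, size)
                k <- k + 1L
                tid <- sprintf("DES:%s:%s:%d", cmp, cl, r)
                rows[[k]] <- add_term(tid,
                    sample(.ONTOLOGY_SOURCES, 1L),
                    paste("designed", cl, "term", r, "for", cmp),
                    mem, stats::runif(1, 0.3, 0.8))
                members_list[[k]] <- mem
                truth_rows[[k]] <- data.frame(term_id = tid,
                    comparison = cmp, true_class = cl,
                    stringsAsFactors = FALSE)
            }
        }
    }
    n_low <- round(n_null_terms * low_coverage_fraction)
    for (r in seq_len(n_null_terms)) {
        size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
        size <- min(size, length(ids))
        mem <- sample(ids, size)
        cov <- if (r <= n_low) stats::runif(1, 0.1, 0.2) else
            stats::runif(1, 0.3, 0.9)
        k <- k + 1L
        tid <- sprintf("NULL:%04d", r)
        rows[[k]] <- add_term(tid, sample(.ONTOLOGY_SOURCES, 1L),
                              paste("null term", r), mem, cov)
        members_list[[k]] <- mem
        truth_rows[[k]] <- data.frame(term_id = tid,
            comparison = NA_character_, true_class = NA_character_,
            stringsAsFactors = FALSE)
    }
    terms <- do.call(rbind, rows)
    terms$coverage <- terms$observed_count / terms$background_count
    terms$proteins <- members_list
    list(terms = terms,
         term_truth = do.call(rbind, truth_rows))
}
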