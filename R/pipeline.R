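#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates every stage end to end: ground-truth simulation, labeling
#' time courses, per-peptide rate fitting with quality filtering, the eight
#' label-free abundance datasets through the normalization chain and
#' differential tests, cross-dataset fold-change averaging, fold-change
#' scaling (range scaling for abundance, auto scaling for turnover),
#' ontology aggregation with one-sample testing, Benjamini-Hochberg
#' correction and representative selection, and quadrant classification.
#' One \linkS4class{ComparisonResult} is produced per non-control genotype.
#'
#' @param config a [simulationConfig()].
#' @param overlap_threshold percent overlap for [selectRepresentatives()].
#' @param outdir optional directory; when given, summary tables are written
#'   as tab-separated files and figures rendered into it.
#' @param render logical; render figures when \code{outdir} is given.
#' @return list with \code{truth} (the \code{"GroundTruth"}),
#'   \code{rates} (named list per genotype of accepted rate fits),
#'   \code{annotations} (the simulated ontology tables) and
#'   \code{comparisons} (named list of \code{ComparisonResult}).
#' @examples
#' cfg <- simulationConfig(n_proteins = 60, seed = 1,
#'     fraction_new_noise_sd = 0, abundance_noise_sd = 0.05,
#'     missing_rate = 0)
#' res <- runPipeline(cfg)
#' res$comparisons$E2vsE3
#' @export
runPipeline <- function(config, overlap_threshold = 75, outdir = NULL,
                        render = !is.null(outdir)) {
    stopifnot(inherits(config, "SimulationConfig"))
    truth <- simulateGroundTruth(config)
    tcs <- simulateLabelTimecourses(truth, config)
    rates <- lapply(split(tcs, tcs$genotype), function(d) {
        filterRateFits(fitProteinRates(d))$accepted
    })
    datasets <- simulateAbundanceDatasets(truth, config)
    normalized <- lapply(datasets, function(ae) {
        knnImpute(slopeNormalize(log2AndCenter(filterMissingness(ae))))
    })
    annotations <- simulateOntologyAnnotations(truth, config)
    terms <- coverageFilter(annotations$terms)
    exp_genos <- setdiff(config$genotypes, config$control)
    comparisons <- list()
    for (g in exp_genos) {
        label <- paste0(g, "vs", config$control)
        diffs <- do.call(rbind, lapply(normalized, differentialTest,
                                       exp_genotype = g,
                                       ctrl_genotype = config$control))
        afc <- averageFC(diffs)
        afc$scaled_fc <- rangeScale(afc$mean_log2_fc)
        tfc <- computeTurnoverFC(rates[[g]], rates[[config$control]])
        if (nrow(tfc) >= 2L) {
            tfc$scaled_fc <- autoScale(tfc$log2_rate_fc)
        } else if (nrow(tfc)) {
            tfc$scaled_fc <- NA_real_
        }
        ont <- summarizeOntology(terms, afc, tfc)
        ont <- selectRepresentatives(ont, terms, overlap_threshold)
        comparisons[[label]] <- buildComparison(
            afc, tfc, ont, terms, label,
            config = config, seed = config$seed)
    }
    out <- list(truth = truth, rates = rates, annotations = annotations,
                comparisons = comparisons)
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (label in names(comparisons)) {
            cmp <- comparisons[[label]]
            writeTable(abundanceFC(cmp),
                       file.path(outdir, paste0("abundance_fc_", label,
                                                ".tsv")))
            writeTable(turnoverFC(cmp),
                       file.path(outdir, paste0("turnover_fc_", label,
                                                ".tsv")))
            writeOntologySummary(ontologySummary(cmp),
                file.path(outdir, paste0("ontology_summary_", label,
                                         ".csv")))
            if (render) renderFigures(cmp, outdir)
        }
        writeRunManifest(out, file.path(outdir, "run_manifest.txt"))
    }
    out
}

#' Evaluate regulation-class recovery against the ground truth
#'
#' Compares the regulation class assigned to each designed ontology term
#' with the class it was constructed from, per comparison.
#'
#' @param result the list returned by [runPipeline()].
#' @return data.frame with \code{term_id}, \code{comparison},
#'   \code{true_class}, \code{called_class}, \code{correct}; terms designed
#'   for a comparison but absent from its summary get NA calls.
#' @export
evaluateClassRecovery <- function(result) {
    tt <- result$annotations$term_truth
    tt <- tt[!is.na(tt$comparison), , drop = FALSE]
    rows <- lapply(seq_len(nrow(tt)), function(i) {
        cmp <- result$comparisons[[tt$comparison[i]]]
        ont <- ontologySummary(cmp)
        j <- match(tt$term_id[i], ont$term_id)
        called <- if (is.na(j)) NA_character_ else ont$regulation_class[j]
        data.frame(term_id = tt$term_id[i], comparison = tt$comparison[i],
                   true_class = tt$true_class[i], called_class = called,
                   correct = identical(called, tt$true_class[i]),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
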