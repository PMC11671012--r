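## Plain-text readers and writers for the table dialects the pipeline
## consumes and emits: peptide time-course TSVs, abundance TSVs with sample
## metadata, rate tables in the style of a kinetics-software
## "calculated_rates" export, fold-change tables and ontology summaries.

#' Write a data.frame as a tab-separated file
#'
#' @param x data.frame (list columns are collapsed with commas).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTable <- function(x, path) {
    for (cn in names(x)) {
        if (is.list(x[[cn]])) {
            x[[cn]] <- vapply(x[[cn]], paste, character(1), collapse = ",")
        }
    }
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a peptide labeling time-course table
#'
#' Expects tab-separated columns \code{protein_id}, \code{peptide_id},
#' \code{time_days}, \code{fraction_new} and optionally \code{n_value}.
#'
#' @param path input path.
#' @return data.frame suitable for [fitProteinRates()].
#' @export
readTimeCourses <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "peptide_id", "time_days", "fraction_new")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
        stop("time-course table is missing column(s): ",
             paste(miss, collapse = ", "))
    }
    df
}

#' Read an abundance table plus sample metadata into an AbundanceExperiment
#'
#' The abundance table has a \code{protein_id} column and one column per
#' sample (blank/NA = missing area); the metadata table has
#' \code{sample_id}, \code{genotype} and optionally \code{sex},
#' \code{block}, \code{fraction}, \code{timepoint_days}.
#'
#' @param area_path path of the abundance TSV.
#' @param meta_path path of the sample-metadata TSV.
#' @param dataset_id optional dataset label.
#' @return an \linkS4class{AbundanceExperiment} at stage \code{"raw"}.
#' @export
readAbundanceTable <- function(area_path, meta_path,
                               dataset_id = NA_character_) {
    ar <- utils::read.delim(area_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!"protein_id" %in% names(ar)) {
        stop("abundance table needs a protein_id column")
    }
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "genotype") %in% names(meta))) {
        stop("sample metadata needs sample_id and genotype columns")
    }
    m <- as.matrix(ar[, setdiff(names(ar), "protein_id"), drop = FALSE])
    rownames(m) <- ar$protein_id
    miss <- setdiff(colnames(m), meta$sample_id)
    if (length(miss)) {
        stop("samples without metadata: ", paste(miss, collapse = ", "))
    }
    meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
    AbundanceExperiment(m, meta, dataset_id = dataset_id)
}

#' Write a rate table in the kinetics-export style
#'
#' Combines accepted and rejected protein fits into one table with columns
#' \code{protein_id}, \code{rate_per_day}, \code{rsq},
#' \code{n_unique_peptides}, \code{asymptote}, \code{deviation},
#' \code{accepted}, \code{rejection_reason}.
#'
#' @param filtered list from [filterRateFits()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRateTable <- function(filtered, path) {
    acc <- filtered$accepted
    rej <- filtered$rejected
    if (nrow(acc)) {
        acc$accepted <- TRUE
        acc$rejection_reason <- NA_character_
    }
    if (nrow(rej)) {
        rej$accepted <- FALSE
    }
    cols <- c("protein_id", "rate_per_day", "rsq", "n_unique_peptides",
              "asymptote", "deviation", "accepted", "rejection_reason")
    out <- rbind(acc[intersect(cols, names(acc))],
                 rej[intersect(cols, names(rej))])
    writeTable(out[order(out$protein_id), , drop = FALSE], path)
}

#' Write an ontology summary as CSV
#'
#' @param summary data.frame from [summarizeOntology()] /
#'   [selectRepresentatives()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeOntologySummary <- function(summary, path) {
    utils::write.csv(summary, path, row.names = FALSE, quote = TRUE,
                     na = "")
    invisible(path)
}

#' Write a run manifest
#'
#' Records the seed, configuration (key = value lines), configuration hash
#' and per-stage record counts of a pipeline run as structured plain text.
#'
#' @param result list returned by [runPipeline()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRunManifest <- function(result, path) {
    cfg <- result$truth$config
    lines <- c(
        "[run]",
        paste0("package_version = ",
               as.character(utils::packageVersion("ProteoTurn"))),
        paste0("seed = ", cfg$seed),
        paste0("config_hash = ", .configHash(cfg)),
        "",
        "[config]",
        vapply(names(cfg), function(k) {
            paste0(k, " = ", paste(cfg[[k]], collapse = ","))
        }, character(1)),
        "",
        "[counts]",
        paste0("n_proteins = ", cfg$n_proteins),
        vapply(names(result$rates), function(g) {
            paste0("n_rates_", g, " = ", nrow(result$rates[[g]]))
        }, character(1)),
        vapply(names(result$comparisons), function(lb) {
            cmp <- result$comparisons[[lb]]
            paste0("n_significant_terms_", lb, " = ",
                   cmp@provenance$n_significant_terms)
        }, character(1))
    )
    writeLines(lines, path)
    invisible(path)
}

#' Write an enrichment table in the StringDB-export dialect
#'
#' @param terms data.frame with term fields and a \code{proteins} list
#'   column (as from [simulateOntologyAnnotations()]).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEnrichmentTable <- function(terms, path) {
    out <- data.frame(
        `term ID` = terms$term_id,
        category = terms$source,
        `term description` = terms$description,
        `observed gene count` = terms$observed_count,
        `background gene count` = terms$background_count,
        `matching proteins in your network (labels)` =
            vapply(terms$proteins, paste, character(1), collapse = ","),
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
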