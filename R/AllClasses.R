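#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.ABUNDANCE_STAGES <- c("raw", "log2", "centered", "slope_normalized", "imputed")

#' Protein abundance experiment with staged normalization state
#'
#' An \code{AbundanceExperiment} is a
#' \linkS4class{SummarizedExperiment} holding one protein-by-sample matrix of
#' label-free quantification values (chromatographic peak "Area" on the raw
#' stage, normalized log2 values afterwards) together with the sample
#' annotation needed by the normalization chain. The \code{stage} slot records
#' how far along the chain (\code{raw}, \code{log2}, \code{centered},
#' \code{slope_normalized}, \code{imputed}) the assay has been taken; each
#' transform checks the stage of its input and advances it, so a matrix cannot
#' be, say, imputed twice or centered after imputation.
#'
#' @slot stage character(1), one of \code{"raw"}, \code{"log2"},
#'   \code{"centered"}, \code{"slope_normalized"}, \code{"imputed"}.
#'
#' @seealso [filterMissingness()], [log2AndCenter()], [slopeNormalize()],
#'   [knnImpute()], [differentialTest()]
#' @export
setClass("AbundanceExperiment",
    contains = "SummarizedExperiment",
    representation(stage = "character"),
    prototype(stage = "raw")
)

setValidity("AbundanceExperiment", function(object) {
    msg <- NULL
    if (length(object@stage) != 1L || !object@stage %in% .ABUNDANCE_STAGES) {
        msg <- c(msg, paste0("stage must be one of: ",
            paste(.ABUNDANCE_STAGES, collapse = ", ")))
    }
    if (!"genotype" %in% colnames(colData(object))) {
        msg <- c(msg, "colData must contain a 'genotype' column")
    }
    if (nrow(object) > 0L && ncol(object) > 0L) {
        v <- assay(object)
        if (identical(object@stage, "imputed") && anyNA(v)) {
            msg <- c(msg, "imputed stage must contain no missing values")
        }
        if (object@stage %in% c("centered", "slope_normalized")) {
            mu <- colMeans(v, na.rm = TRUE)
            if (any(abs(mu) > 1e-8)) {
                msg <- c(msg, "per-sample means must be 0 after centering")
            }
        }
        if (identical(object@stage, "raw") && any(v[!is.na(v)] < 0)) {
            msg <- c(msg, "raw areas must be non-negative")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an AbundanceExperiment
#'
#' @param areas numeric matrix, proteins in rows and samples in columns;
#'   missing measurements as \code{NA}. Row names are protein identifiers,
#'   column names sample identifiers.
#' @param sampleData data.frame or DataFrame with one row per column of
#'   \code{areas}; must contain a \code{genotype} column and typically
#'   \code{sex}, \code{block}, \code{fraction} and \code{timepoint_days}.
#' @param stage normalization stage of \code{areas}; defaults to
#'   \code{"raw"}.
#' @param dataset_id optional dataset label stored in the object metadata.
#'
#' @return An \linkS4class{AbundanceExperiment}.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'     dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' ae <- AbundanceExperiment(m,
#'     data.frame(genotype = c("E2", "E2", "E3", "E3")))
#' abundanceStage(ae)
#' @export
AbundanceExperiment <- function(areas, sampleData, stage = "raw",
                                dataset_id = NA_character_) {
    areas <- as.matrix(areas)
    if (is.null(rownames(areas))) {
        rownames(areas) <- paste0("protein_", seq_len(nrow(areas)))
    }
    if (is.null(colnames(areas))) {
        colnames(areas) <- paste0("sample_", seq_len(ncol(areas)))
    }
    cd <- as(sampleData, "DataFrame")
    rownames(cd) <- colnames(areas)
    se <- SummarizedExperiment(assays = list(area = areas), colData = cd)
    obj <- new("AbundanceExperiment", se, stage = stage)
    metadata(obj)$dataset_id <- dataset_id
    obj
}

#' @describeIn AbundanceExperiment current normalization stage.
#' @param object an \code{AbundanceExperiment}.
#' @export
abundanceStage <- function(object) {
    stopifnot(is(object, "AbundanceExperiment"))
    object@stage
}

#' Dataset identifier of an AbundanceExperiment
#'
#' @param object an \code{AbundanceExperiment}.
#' @return character(1) dataset label (NA if unset).
#' @export
datasetId <- function(object) {
    stopifnot(is(object, "AbundanceExperiment"))
    id <- metadata(object)$dataset_id
    if (is.null(id)) NA_character_ else id
}

## advance stage, enforcing forward-only transitions
.advanceStage <- function(object, from, to) {
    if (!object@stage %in% from) {
        stop("operation requires stage ", paste(sQuote(from), collapse = " or "),
             " but object is at stage ", sQuote(object@stage))
    }
    object@stage <- to
    validObject(object)
    object
}

setMethod("show", "AbundanceExperiment", function(object) {
    cat("AbundanceExperiment (stage: ", object@stage, ")\n", sep = "")
    cat("  dataset: ", datasetId(object), "\n", sep = "")
    callNextMethod()
})

#' Joined abundance/turnover comparison result
#'
#' Container for one experimental-vs-control comparison: the protein-level
#' scaled abundance and turnover fold-change tables, the ontology-level
#' summary (means, tests, regulation classes), the ontology membership table
#' used to build it, and provenance (seed, configuration hash, package
#' version).
#'
#' @slot label character(1) comparison label, e.g. \code{"E2vsE3"}.
#' @slot abundanceFC data.frame of per-protein abundance fold changes
#'   (\code{protein_id}, \code{mean_log2_fc}, \code{scaled_fc},
#'   \code{n_datasets}).
#' @slot turnoverFC data.frame of per-protein turnover-rate fold changes
#'   (\code{protein_id}, \code{log2_rate_fc}, \code{scaled_fc}).
#' @slot ontology data.frame of per-term summaries as returned by
#'   [summarizeOntology()] (plus \code{representative_of} after
#'   [selectRepresentatives()]).
#' @slot terms data.frame of ontology terms with a \code{proteins} list
#'   column (membership), used for overlap heatmaps.
#' @slot provenance named list (seed, config hash, package version).
#'
#' @seealso [buildComparison()], [renderFigures()]
#' @export
setClass("ComparisonResult",
    representation(
        label = "character",
        abundanceFC = "data.frame",
        turnoverFC = "data.frame",
        ontology = "data.frame",
        terms = "data.frame",
        provenance = "list"
    )
)

setValidity("ComparisonResult", function(object) {
    msg <- NULL
    if (length(object@label) != 1L || !nzchar(object@label)) {
        msg <- c(msg, "label must be a non-empty string")
    }
    need <- c("protein_id", "mean_log2_fc", "scaled_fc")
    if (nrow(object@abundanceFC) > 0L &&
        !all(need %in% names(object@abundanceFC))) {
        msg <- c(msg, "abundanceFC must have protein_id/mean_log2_fc/scaled_fc")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ComparisonResult", function(object) {
    cat("ComparisonResult:", object@label, "\n")
    cat("  proteins with abundance FC:", nrow(object@abundanceFC), "\n")
    cat("  proteins with turnover FC: ", nrow(object@turnoverFC), "\n")
    n_sig <- sum(object@ontology$significant %in% TRUE &
                 is.na(object@ontology$representative_of))
    cat("  ontology terms:", nrow(object@ontology),
        "(significant, non-redundant:", n_sig, ")\n")
})

#' @describeIn ComparisonResult comparison label accessor.
#' @param object a \code{ComparisonResult}.
#' @export
comparisonLabel <- function(object) object@label

#' Accessors for ComparisonResult tables
#'
#' @param object a \linkS4class{ComparisonResult}.
#' @return the requested data.frame.
#' @name comparison-accessors
NULL

#' @rdname comparison-accessors
#' @export
abundanceFC <- function(object) object@abundanceFC

#' @rdname comparison-accessors
#' @export
turnoverFC <- function(object) object@turnoverFC

#' @rdname comparison-accessors
#' @export
ontologySummary <- function(object) object@ontology

#' @rdname comparison-accessors
#' @export
ontologyTerms <- function(object) object@terms
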