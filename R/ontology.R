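## Ontology-level aggregation: scaled protein fold changes are averaged over
## the member proteins of each functional term (GO, KEGG, Reactome,
## WikiPathways), the term means are tested against zero with a one-sample
## t-test, Benjamini-Hochberg corrected, and redundant near-duplicate terms
## are collapsed to the largest representative.

.ONTOLOGY_SOURCES <- c("GO Process", "GO Function", "GO Component",
                       "KEGG", "Reactome", "WikiPathways")

## tolerant column lookup: StringDB-style spaced headers or snake_case
.findColumn <- function(df, candidates, what) {
    nm <- names(df)
    hit <- which(tolower(nm) %in% tolower(candidates))
    if (length(hit) == 0L) {
        stop("enrichment table is missing column ", sQuote(what))
    }
    nm[hit[1]]
}

#' Parse a functional-enrichment export into ontology terms
#'
#' Reads a StringDB-multiprotein-style table (term id, source database,
#' description, observed and background gene counts, comma-separated member
#' protein labels), restricts it to the six curated source databases
#' (GO Process, GO Function, GO Component, KEGG, Reactome, WikiPathways)
#' and validates the counts against the label lists. Spaced StringDB
#' headers (e.g. \code{"observed gene count"}) and snake_case equivalents
#' are both accepted.
#'
#' @param x path to a tab-separated file, or a data.frame already read.
#' @return data.frame with \code{term_id}, \code{source},
#'   \code{description}, \code{observed_count}, \code{background_count},
#'   \code{coverage} and a \code{proteins} list column; the number of rows
#'   skipped for a non-curated source is in the \code{"n_skipped_source"}
#'   attribute.
#' @export
parseEnrichmentTable <- function(x) {
    df <- if (is.character(x)) {
        utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
        as.data.frame(x, check.names = FALSE)
    }
    c_id <- .findColumn(df, c("term_id", "term id", "#term id"), "term_id")
    c_src <- .findColumn(df, c("source", "category", "#category"), "source")
    c_desc <- .findColumn(df, c("description", "term description"),
                          "description")
    c_obs <- .findColumn(df, c("observed_gene_count", "observed gene count"),
                         "observed gene count")
    c_bg <- .findColumn(df, c("background_gene_count",
                              "background gene count"),
                        "background gene count")
    c_lab <- .findColumn(df,
        c("matching_proteins_labels",
          "matching proteins in your network (labels)"),
        "matching proteins in your network (labels)")
    keep <- df[[c_src]] %in% .ONTOLOGY_SOURCES
    skipped <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    proteins <- lapply(strsplit(as.character(df[[c_lab]]), ","), trimws)
    observed <- as.integer(df[[c_obs]])
    background <- as.integer(df[[c_bg]])
    bad <- which(observed != lengths(proteins))
    if (length(bad)) {
        stop("term ", df[[c_id]][bad[1]], ": observed gene count ",
             observed[bad[1]], " does not match ", lengths(proteins)[bad[1]],
             " protein labels")
    }
    if (any(observed <= 0L) || any(observed > background)) {
        stop("observed gene counts must satisfy 0 < observed <= background")
    }
    out <- data.frame(
        term_id = as.character(df[[c_id]]),
        source = as.character(df[[c_src]]),
        description = as.character(df[[c_desc]]),
        observed_count = observed,
        background_count = background,
        coverage = observed / background,
        stringsAsFactors = FALSE
    )
    out$proteins <- proteins
    rownames(out) <- NULL
    attr(out, "n_skipped_source") <- skipped
    out
}

#' Coverage filter for ontology terms
#'
#' Keeps terms whose observed member count is at least \code{min_coverage}
#' of the background gene count (boundary inclusive), ensuring the term is
#' well represented in the measured proteome.
#'
#' @param terms data.frame from [parseEnrichmentTable()].
#' @param min_coverage minimum coverage fraction (default 0.25).
#' @return the retained terms.
#' @export
coverageFilter <- function(terms, min_coverage = 0.25) {
    out <- terms[terms$coverage >= min_coverage, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Mean scaled fold changes of one term's member proteins
#'
#' @param proteins character vector of member protein identifiers.
#' @param abundance_fc data.frame with \code{protein_id} and
#'   \code{scaled_fc} (scaled abundance fold changes).
#' @param turnover_fc data.frame with \code{protein_id} and
#'   \code{scaled_fc} (scaled turnover fold changes), or NULL.
#' @return list with \code{n_abund}, \code{mean_dabundance},
#'   \code{abund_values} (member scaled abundance FCs), \code{n_turn},
#'   \code{mean_dturnover} (NA when no member has a turnover FC).
#' @export
summarizeTerm <- function(proteins, abundance_fc, turnover_fc = NULL) {
    av <- abundance_fc$scaled_fc[match(proteins, abundance_fc$protein_id)]
    av <- av[!is.na(av)]
    tv <- numeric(0)
    if (!is.null(turnover_fc) && nrow(turnover_fc)) {
        tv <- turnover_fc$scaled_fc[match(proteins, turnover_fc$protein_id)]
        tv <- tv[!is.na(tv)]
    }
    list(
        n_abund = length(av),
        mean_dabundance = if (length(av)) mean(av) else NA_real_,
        abund_values = av,
        n_turn = length(tv),
        mean_dturnover = if (length(tv)) mean(tv) else NA_real_
    )
}

#' One-sample t-test against zero
#'
#' Two-sided test of the mean of \code{values} against 0 (delegated to
#' \code{\link[stats]{t.test}}). With fewer than 2 values or zero sample
#' standard deviation the test is undefined and NA statistics are returned
#' with \code{defined = FALSE} (the term is still reported, just untested).
#'
#' @param values numeric vector.
#' @return list with \code{t_stat}, \code{p_value}, \code{defined}.
#' @export
oneSampleTest <- function(values) {
    values <- values[is.finite(values)]
    if (length(values) < 2L || stats::sd(values) == 0) {
        return(list(t_stat = NA_real_, p_value = NA_real_, defined = FALSE))
    }
    ht <- stats::t.test(values, mu = 0)
    list(t_stat = unname(ht$statistic), p_value = ht$p.value, defined = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (delegated to
#' \code{\link[stats]{p.adjust}} with \code{method = "BH"}), returned in
#' input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p_values) {
    if (length(p_values) == 0L) return(numeric(0))
    if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
        stop("p-values must lie in [0, 1]")
    }
    stats::p.adjust(p_values, method = "BH")
}

#' Ontology-level summary of scaled fold changes
#'
#' For every term, averages the scaled abundance and turnover fold changes
#' of its member proteins (membership intersected with the available FC
#' tables), tests the member abundance values against zero with a
#' one-sample t-test, adjusts the p-values of all tested terms as one
#' Benjamini-Hochberg family, flags terms with adjusted p below
#' \code{alpha} as significant, and assigns a regulation class from the
#' signs of the two means ([classifyRegulation()]). Turnover means are
#' descriptive only and are not themselves tested; terms with no member
#' turnover FC get an NA turnover mean and class \code{indeterminate}.
#' Terms with no member abundance FC are skipped (counted in the
#' \code{"n_skipped_no_fc"} attribute).
#'
#' @param terms data.frame from [parseEnrichmentTable()] (after
#'   [coverageFilter()]).
#' @param abundance_fc data.frame with \code{protein_id}, \code{scaled_fc}.
#' @param turnover_fc data.frame with \code{protein_id}, \code{scaled_fc},
#'   or NULL.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame with one row per summarized term: term fields plus
#'   \code{n_abund}, \code{mean_dabundance}, \code{n_turn},
#'   \code{mean_dturnover}, \code{t_stat}, \code{p_value}, \code{bh_pv},
#'   \code{significant}, \code{regulation_class}.
#' @export
summarizeOntology <- function(terms, abundance_fc, turnover_fc = NULL,
                              alpha = 0.05) {
    rows <- vector("list", nrow(terms))
    for (i in seq_len(nrow(terms))) {
        s <- summarizeTerm(terms$proteins[[i]], abundance_fc, turnover_fc)
        if (s$n_abund == 0L) next
        ht <- oneSampleTest(s$abund_values)
        rows[[i]] <- data.frame(
            term_id = terms$term_id[i],
            source = terms$source[i],
            description = terms$description[i],
            observed_count = terms$observed_count[i],
            background_count = terms$background_count[i],
            coverage = terms$coverage[i],
            n_abund = s$n_abund,
            mean_dabundance = s$mean_dabundance,
            n_turn = s$n_turn,
            mean_dturnover = s$mean_dturnover,
            t_stat = ht$t_stat,
            p_value = ht$p_value,
            stringsAsFactors = FALSE
        )
    }
    skipped <- sum(vapply(rows, is.null, logical(1)))
    out <- do.call(rbind, rows)
    if (is.null(out)) {
        out <- data.frame(term_id = character(0))
        attr(out, "n_skipped_no_fc") <- skipped
        return(out)
    }
    out$bh_pv <- NA_real_
    tested <- !is.na(out$p_value)
    out$bh_pv[tested] <- bhAdjust(out$p_value[tested])
    out$significant <- !is.na(out$bh_pv) & out$bh_pv < alpha
    out$regulation_class <- classifyRegulation(out$mean_dabundance,
                                               out$mean_dturnover)
    rownames(out) <- NULL
    attr(out, "n_skipped_no_fc") <- skipped
    out
}

#' Pairwise protein-overlap matrix of ontology terms
#'
#' Row-normalized, asymmetric percentages: entry (A, B) is
#' \code{100 * |A intersect B| / |A|}; the diagonal is 100.
#'
#' @param terms data.frame with \code{term_id} and a \code{proteins} list
#'   column.
#' @return numeric matrix of percentages with term ids as dimnames.
#' @export
overlapMatrix <- function(terms) {
    stopifnot(nrow(terms) >= 1L)
    sets <- lapply(terms$proteins, unique)
    n <- length(sets)
    m <- matrix(0, n, n, dimnames = list(terms$term_id, terms$term_id))
    for (a in seq_len(n)) {
        for (b in seq_len(n)) {
            m[a, b] <- 100 * length(intersect(sets[[a]], sets[[b]])) /
                length(sets[[a]])
        }
        m[a, a] <- 100
    }
    m
}

#' Collapse redundant significant terms to representatives
#'
#' Among significant terms, near-duplicates (row-wise protein overlap above
#' \code{overlap_threshold} percent with an already-kept term) are dropped
#' in favour of the term with the most member proteins
#' (\code{n_abund}; ties broken lexicographically by term id). Dropped
#' terms are annotated with their representative; non-significant terms
#' pass through untouched.
#'
#' @param summaries data.frame from [summarizeOntology()].
#' @param terms data.frame with \code{term_id} and \code{proteins} list
#'   column supplying membership.
#' @param overlap_threshold percent overlap above which two terms are
#'   considered redundant (default 75).
#' @return \code{summaries} with an added \code{representative_of} column
#'   (NA for retained terms, the representative's term id for dropped
#'   significant terms).
#' @export
selectRepresentatives <- function(summaries, terms, overlap_threshold = 75) {
    summaries$representative_of <- NA_character_
    sig <- which(summaries$significant %in% TRUE)
    if (length(sig) < 2L) return(summaries)
    ord <- sig[order(-summaries$n_abund[sig], summaries$term_id[sig])]
    sets <- lapply(terms$proteins[match(summaries$term_id,
                                        terms$term_id)], unique)
    kept <- integer(0)
    for (i in ord) {
        if (length(kept)) {
            ov <- vapply(kept, function(b) {
                100 * length(intersect(sets[[i]], sets[[b]])) /
                    length(sets[[i]])
            }, numeric(1))
            if (any(ov > overlap_threshold)) {
                rep_idx <- kept[which.max(ov)]
                summaries$representative_of[i] <- summaries$term_id[rep_idx]
                next
            }
        }
        kept <- c(kept, i)
    }
    summaries
}
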