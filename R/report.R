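## Quadrant classification and reporting. The sign pair
## (delta-abundance, delta-turnover) identifies the regulatory mode:
## abundance up with turnover up means more synthesis, abundance up with
## turnover down means less degradation, and mirror-image for decreases.

#' Classify regulation mode from the signs of the two fold changes
#'
#' Maps the sign pair of the mean scaled abundance and turnover fold
#' changes to a regulation class: (+, +) increased synthesis, (+, -)
#' decreased degradation, (-, +) increased degradation, (-, -) decreased
#' synthesis. Magnitude plays no role beyond an optional dead zone
#' \code{epsilon}: values whose magnitude is at most \code{epsilon}
#' (default 0, i.e. exact zeros) and missing values give
#' \code{"indeterminate"}. Vectorized over both arguments.
#'
#' @param mean_dabundance mean scaled abundance fold change(s).
#' @param mean_dturnover mean scaled turnover fold change(s).
#' @param epsilon dead zone half-width (default 0).
#' @return character vector of regulation classes.
#' @examples
#' classifyRegulation(0.3, 0.2)  # "synthesis_up"
#' classifyRegulation(0.3, -0.2) # "degradation_down"
#' @export
classifyRegulation <- function(mean_dabundance, mean_dturnover,
                               epsilon = 0) {
    n <- max(length(mean_dabundance), length(mean_dturnover))
    da <- rep_len(mean_dabundance, n)
    dt <- rep_len(mean_dturnover, n)
    out <- rep("indeterminate", n)
    ok <- !is.na(da) & !is.na(dt) & abs(da) > epsilon & abs(dt) > epsilon
    out[ok & da > 0 & dt > 0] <- "synthesis_up"
    out[ok & da > 0 & dt < 0] <- "degradation_down"
    out[ok & da < 0 & dt > 0] <- "degradation_up"
    out[ok & da < 0 & dt < 0] <- "synthesis_down"
    out
}

.configHash <- function(x) {
    f <- tempfile(fileext = ".rds")
    on.exit(unlink(f))
    saveRDS(x, f)
    unname(tools::md5sum(f))
}

#' Assemble a comparison result
#'
#' Joins the protein-level abundance and turnover fold-change tables with
#' the ontology summary for one comparison into a
#' \linkS4class{ComparisonResult}, validating that they belong together.
#' Disjoint protein sets between the two FC tables trigger a warning with
#' counts; summary counts (proteins with both FCs, significant terms) are
#' recorded in the provenance.
#'
#' @param abundance_fc data.frame with \code{protein_id},
#'   \code{mean_log2_fc}, \code{scaled_fc}, \code{n_datasets}.
#' @param turnover_fc data.frame with \code{protein_id},
#'   \code{log2_rate_fc}, \code{scaled_fc} (may be empty).
#' @param ontology data.frame from [summarizeOntology()] (after
#'   [selectRepresentatives()] if redundancy was resolved).
#' @param terms ontology membership table (for overlap heatmaps).
#' @param label comparison label, e.g. \code{"E2vsE3"}.
#' @param config optional configuration object hashed into the provenance.
#' @param seed optional seed recorded in the provenance.
#' @return a \linkS4class{ComparisonResult}.
#' @export
buildComparison <- function(abundance_fc, turnover_fc, ontology, terms,
                            label, config = NULL, seed = NA_integer_) {
    shared <- intersect(abundance_fc$protein_id, turnover_fc$protein_id)
    if (nrow(turnover_fc) > 0L && length(shared) == 0L) {
        warning("abundance and turnover tables share no protein (",
                nrow(abundance_fc), " vs ", nrow(turnover_fc), " entries)")
    }
    if (nrow(ontology) > 0L && "n_abund" %in% names(ontology) &&
        any(ontology$n_abund > nrow(abundance_fc))) {
        stop("ontology summary references more proteins than the FC table")
    }
    prov <- list(
        seed = seed,
        config_hash = if (is.null(config)) NA_character_ else
            .configHash(config),
        package_version = as.character(utils::packageVersion("ProteoTurn")),
        n_proteins_abundance = nrow(abundance_fc),
        n_proteins_turnover = nrow(turnover_fc),
        n_proteins_both = length(shared),
        n_significant_terms = sum(ontology$significant %in% TRUE)
    )
    new("ComparisonResult", label = label, abundanceFC = abundance_fc,
        turnoverFC = turnover_fc, ontology = ontology, terms = terms,
        provenance = prov)
}

.openDevice <- function(path, format, width, height) {
    switch(format,
        svg = grDevices::svg(path, width = width, height = height),
        png = grDevices::png(path, width = width * 100,
                             height = height * 100, res = 100),
        stop("unsupported figure format: ", format))
}

.saveFigure <- function(plot, stem, outdir, formats, width, height) {
    paths <- character(0)
    for (fmt in formats) {
        path <- file.path(outdir, paste0(stem, ".", fmt))
        .openDevice(path, fmt, width, height)
        print(plot)
        grDevices::dev.off()
        paths <- c(paths, path)
    }
    paths
}

#' Render the comparison figures
#'
#' Writes, for one comparison: (i) the proteostasis scatter of ontology
#' terms (x = mean scaled delta-abundance, y = mean scaled delta-turnover,
#' significant terms highlighted); (ii) paired bar charts of
#' delta-abundance (orange) and delta-turnover (blue) for each significant
#' non-redundant ontology, labelled \code{"description (n)"} with the
#' member protein count; (iii) the protein-overlap heatmap of those terms.
#' With no significant terms the scatter is still rendered and the bars and
#' heatmap are skipped with a message. Layout is deterministic given the
#' input.
#'
#' @param result a \linkS4class{ComparisonResult}.
#' @param outdir output directory (created if needed).
#' @param formats figure formats, subset of \code{c("svg", "png")}.
#' @param width,height device size in inches.
#' @return invisibly, the paths of the written files.
#' @export
renderFigures <- function(result, outdir, formats = c("svg", "png"),
                          width = 7, height = 5) {
    stopifnot(is(result, "ComparisonResult"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ont <- result@ontology
    label <- result@label
    paths <- character(0)

    scat <- ont[!is.na(ont$mean_dabundance) & !is.na(ont$mean_dturnover), ]
    p1 <- ggplot2::ggplot(scat,
            ggplot2::aes(x = .data$mean_dabundance,
                         y = .data$mean_dturnover,
                         color = .data$significant)) +
        ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                            color = "grey60") +
        ggplot2::geom_vline(xintercept = 0, linewidth = 0.3,
                            color = "grey60") +
        ggplot2::geom_point(size = 2) +
        ggplot2::scale_color_manual(
            values = c("TRUE" = "#D55E00", "FALSE" = "grey40"),
            na.value = "grey80") +
        ggplot2::labs(x = "mean Δabundance (scaled)",
                      y = "mean Δturnover (scaled)",
                      title = paste("Proteostasis plot:", label)) +
        ggplot2::theme_bw()
    paths <- c(paths, .saveFigure(p1, paste0("proteostasis_", label),
                                  outdir, formats, width, height))

    sig <- ont[ont$significant %in% TRUE, , drop = FALSE]
    if ("representative_of" %in% names(sig)) {
        sig <- sig[is.na(sig$representative_of), , drop = FALSE]
    }
    if (nrow(sig) == 0L) {
        message("no significant ontology terms; bar chart and heatmap ",
                "skipped")
        return(invisible(paths))
    }
    sig$term_label <- paste0(sig$description, " (", sig$n_abund, ")")
    long <- rbind(
        data.frame(term_label = sig$term_label, metric = "Δabundance",
                   value = sig$mean_dabundance),
        data.frame(term_label = sig$term_label, metric = "Δturnover",
                   value = sig$mean_dturnover))
    long <- long[!is.na(long$value), ]
    p2 <- ggplot2::ggplot(long,
            ggplot2::aes(x = .data$term_label, y = .data$value,
                         fill = .data$metric)) +
        ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                          width = 0.7) +
        ggplot2::scale_fill_manual(
            values = c("Δabundance" = "#E69F00",
                       "Δturnover" = "#0072B2")) +
        ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = "mean scaled FC",
                      title = paste("Significant ontologies:", label)) +
        ggplot2::theme_bw()
    paths <- c(paths, .saveFigure(p2, paste0("ontology_bars_", label),
                                  outdir, formats, width,
                                  max(height, 0.35 * nrow(sig) + 1.5)))

    tm <- result@terms[match(sig$term_id, result@terms$term_id), ,
                       drop = FALSE]
    om <- overlapMatrix(tm)
    hm <- data.frame(
        a = rep(rownames(om), times = ncol(om)),
        b = rep(colnames(om), each = nrow(om)),
        pct = as.vector(om))
    p3 <- ggplot2::ggplot(hm, ggplot2::aes(x = .data$b, y = .data$a,
                                           fill = .data$pct)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient(low = "white", high = "#0072B2",
                                     limits = c(0, 100),
                                     name = "% shared",
                                     # vector legend keeps SVG output
                                     # deterministic (no raster element)
                                     guide = ggplot2::guide_colourbar(
                                         display = "rectangles")) +
        ggplot2::labs(x = NULL, y = NULL,
                      title = paste("Protein overlap:", label)) +
        ggplot2::theme_bw() +
        ggplot2::theme(axis.text.x =
            ggplot2::element_text(angle = 45, hjust = 1))
    paths <- c(paths, .saveFigure(p3, paste0("overlap_", label),
                                  outdir, formats, width, height))
    invisible(paths)
}
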