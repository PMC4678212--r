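#' Heat-map panel of log2 ratios for a gene set
#'
#' One row per gene: the AZ/NAZ log2 ratio per time point (AZ-specificity
#' block) followed by the time/0 h block for the AZ tissue, plus marker flags
#' for >8-fold AZ-specific and >8-fold up-regulated genes copied from the
#' classified [differentialTable()]. Rows are ordered by descending maximum
#' time/0 h ratio, ties broken by gene id; pass \code{ordering = "none"} to
#' keep the input order.
#'
#' @param diff a classified [differentialTable()] (after [classifyGenes()]).
#' @param members gene ids to include; empty sets give an empty panel
#'   (logged).
#' @param ordering \code{"maxT0"} (default) or \code{"none"}.
#' @param colorBound symmetric color-scale bound (log2 units); stored as an
#'   attribute for rendering. Defaults to 6 (use 3 for the compressed
#'   Arabidopsis-style scale).
#' @return data.frame with ratio columns, marker columns
#'   \code{marker_az_specific} and \code{marker_changed_up}, and attributes
#'   \code{colorBounds} (symmetric about 0) and \code{blocks}.
#' @export
buildHeatmapPanel <- function(diff, members = rownames(diff),
                              ordering = c("maxT0", "none"),
                              colorBound = 6) {
    ordering <- match.arg(ordering)
    need <- c("az_specific", "changed_up")
    if (!all(need %in% colnames(diff)))
        stop("diff must be classified first (classifyGenes)")
    missing <- setdiff(members, rownames(diff))
    if (length(missing))
        stop("genes absent from diff: ",
             paste(utils::head(missing, 5), collapse = ", "))
    if (!length(members)) message("empty member set: empty heat-map panel")
    md <- metadata(diff)
    azCols <- sprintf("log2_az_naz_t%g", md$times)
    t0Cols <- sprintf("log2_t0_%s_t%g", md$azTissue, md$times[-1])
    panel <- as.data.frame(diff[members, c(azCols, t0Cols), drop = FALSE])
    panel$marker_az_specific <- diff[members, "az_specific"]
    panel$marker_changed_up <- diff[members, "changed_up"]
    if (ordering == "maxT0" && nrow(panel)) {
        key <- apply(as.matrix(panel[t0Cols]), 1L, max)
        panel <- panel[order(-key, rownames(panel)), , drop = FALSE]
    }
    attr(panel, "colorBounds") <- c(-colorBound, colorBound)
    attr(panel, "blocks") <- list(az_naz = azCols, t_over_0 = t0Cols)
    panel
}

#' Time-course table of a gene set's transcriptome share per tissue
#'
#' Serializes one line per tissue of the percent-of-transcriptome trajectory
#' of a gene set (a functional category, its significant subset, or a single
#' gene): per-sample shares averaged over replicates within each (tissue,
#' time) condition.
#'
#' @param x a floored [AZExperiment] restricted to expressed genes.
#' @param geneSet character vector of gene ids.
#' @param tissues tissues to include; defaults to all in the design. An error
#'   is raised if a requested tissue is absent.
#' @param label name recorded in the output's \code{set} column.
#' @return data.frame of (set, tissue, time_h, percent) rows ordered by
#'   tissue then time.
#' @export
buildTimecourseProfile <- function(x, geneSet, tissues = NULL,
                                   label = "gene_set") {
    stopifnot(is(x, "AZExperiment"))
    d <- colData(x)
    if (is.null(tissues)) tissues <- unique(d$tissue)
    absent <- setdiff(tissues, unique(d$tissue))
    if (length(absent))
        stop("tissue(s) missing from the design: ",
             paste(absent, collapse = ", "))
    shares <- transcriptomeShare(x, geneSet)
    rows <- expand.grid(time_h = sort(unique(d$time_h)), tissue = tissues,
                        stringsAsFactors = FALSE)
    rows$percent <- mapply(function(tis, t) {
        mean(shares[d$tissue == tis & d$time_h == t])
    }, rows$tissue, rows$time_h)
    data.frame(set = label, tissue = rows$tissue, time_h = rows$time_h,
               percent = rows$percent, stringsAsFactors = FALSE)
}

#' Volcano table with capped significance
#'
#' X is the log2 fold change oriented WT/mutant; Y is \eqn{-\log_{10} p},
#' capped at \code{cap} (default 4: p-values below 0.0001 are set to 0.0001,
#' which is why capped points align across the top of the plot). The
#' horizontal significance line sits at \eqn{-\log_{10}} of
#' \code{significanceP}.
#'
#' @param diff a [genotypeDifferential()] result (columns \code{log2_fc},
#'   \code{pvalue}).
#' @param cap positive cap on \eqn{-\log_{10} p}.
#' @param significanceP p-value drawn as the significance line (default
#'   0.015).
#' @return data.frame with columns \code{gene}, \code{log2_fc},
#'   \code{neglog10_p} (all \code{<= cap}) and attribute \code{sigLine}.
#' @examples
#' d <- S4Vectors::DataFrame(log2_fc = c(2, -1), pvalue = c(1e-6, 0.5),
#'                           row.names = c("g1", "g2"))
#' buildVolcano(d)$neglog10_p  # 4, 0.301
#' @export
buildVolcano <- function(diff, cap = 4, significanceP = 0.015) {
    if (!is.numeric(cap) || length(cap) != 1L || cap <= 0)
        stop("cap must be a single positive number")
    need <- c("log2_fc", "pvalue")
    if (!all(need %in% colnames(diff)))
        stop("diff must have columns log2_fc and pvalue")
    out <- data.frame(gene = rownames(diff),
                      log2_fc = diff$log2_fc,
                      neglog10_p = pmin(-log10(diff$pvalue), cap),
                      stringsAsFactors = FALSE)
    attr(out, "sigLine") <- -log10(significanceP)
    attr(out, "cap") <- cap
    out
}

#' Render a heat-map panel
#'
#' Thin wrapper over \pkg{pheatmap} drawing the two ratio blocks with a
#' symmetric diverging color scale; the serialized table from
#' [buildHeatmapPanel()] is the authoritative artifact and re-rendering from
#' it is deterministic.
#'
#' @param panel a [buildHeatmapPanel()] result.
#' @param file optional output path (vector formats supported by
#'   \code{pheatmap}).
#' @return the \code{pheatmap} object, invisibly.
#' @export
plotHeatmapPanel <- function(panel, file = NA) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("plotHeatmapPanel needs the pheatmap package")
    blocks <- attr(panel, "blocks")
    bounds <- attr(panel, "colorBounds")
    m <- as.matrix(panel[unlist(blocks)])
    m <- pmin(pmax(m, bounds[1]), bounds[2])
    breaks <- seq(bounds[1], bounds[2], length.out = 101)
    p <- pheatmap::pheatmap(
        m, cluster_rows = FALSE, cluster_cols = FALSE, breaks = breaks,
        color = grDevices::colorRampPalette(c("blue", "white", "red"))(100),
        gaps_col = length(blocks$az_naz), silent = TRUE,
        filename = file)
    invisible(p)
}

#' Render a time-course line graph
#'
#' One line per tissue (solid AZ, dashed/open non-AZ by linetype), percent of
#' transcriptome against hours.
#'
#' @param profile a [buildTimecourseProfile()] result (rows from several sets
#'   may be concatenated; facets split them).
#' @return a ggplot object.
#' @export
plotTimecourse <- function(profile) {
    ggplot2::ggplot(profile,
        ggplot2::aes(x = .data$time_h, y = .data$percent,
                     linetype = .data$tissue, shape = .data$tissue)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::facet_wrap(~set, scales = "free_y") +
        ggplot2::labs(x = "time (h)", y = "% of transcriptome") +
        ggplot2::theme_bw()
}

#' Render a capped volcano plot
#'
#' @param volcano a [buildVolcano()] result.
#' @return a ggplot object with the significance line drawn.
#' @export
plotVolcano <- function(volcano) {
    ggplot2::ggplot(volcano,
        ggplot2::aes(x = .data$log2_fc, y = .data$neglog10_p)) +
        ggplot2::geom_point(alpha = 0.4, size = 0.8) +
        ggplot2::geom_hline(yintercept = attr(volcano, "sigLine"),
                            linetype = "dashed") +
        ggplot2::labs(x = "log2 fold change (WT/mutant)",
                      y = "-log10 p (capped)") +
        ggplot2::theme_bw()
}
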