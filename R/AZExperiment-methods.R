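#' Construct an AZExperiment
#'
#' @param values numeric gene-by-sample matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param design data.frame (or DataFrame) of per-sample metadata with columns
#'   \code{tissue}, \code{time_h}, \code{replicate} and \code{genotype}, one
#'   row per matrix column, in matrix column order or with rownames matching
#'   the sample ids.
#' @param annotation data.frame with columns \code{length_bp} and
#'   \code{description}, one row per gene.
#' @param valueKind what the numbers are: \code{"counts"}, \code{"rpkm"} or
#'   \code{"signal"}.
#' @return an [AZExperiment].
#' @examples
#' m <- matrix(rpois(6, 20), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("AZ_t0_r1", "NAZ_t0_r1")))
#' d <- data.frame(tissue = c("AZ", "NAZ"), time_h = 0, replicate = 1L,
#'                 genotype = "WT", row.names = colnames(m))
#' a <- data.frame(length_bp = c(1000L, 1500L, 2000L), description = "",
#'                 row.names = rownames(m))
#' AZExperiment(m, d, a, "counts")
#' @export
AZExperiment <- function(values, design, annotation = NULL,
                         valueKind = c("counts", "rpkm", "signal")) {
    valueKind <- match.arg(valueKind)
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix must have gene ids as rownames and ",
             "sample ids as colnames")
    design <- as.data.frame(design)
    if (!is.null(rownames(design)) &&
        !identical(rownames(design), as.character(seq_len(nrow(design)))))
        design <- design[colnames(values), , drop = FALSE]
    if (nrow(design) != ncol(values))
        stop("design must have one row per sample column")
    if (is.null(annotation))
        annotation <- data.frame(length_bp = NA_integer_,
                                 description = "",
                                 row.names = rownames(values))[, , drop = FALSE]
    annotation <- as.data.frame(annotation)[rownames(values), , drop = FALSE]
    se <- SummarizedExperiment(
        assays = list(values = values),
        colData = DataFrame(design, row.names = colnames(values)),
        rowData = DataFrame(annotation, row.names = rownames(values)))
    new("AZExperiment", se, valueKind = valueKind)
}

#' @rdname valueKind
#' @export
setMethod("valueKind", "AZExperiment", function(x) x@valueKind)

#' @rdname valueKind
#' @export
setReplaceMethod("valueKind", "AZExperiment", function(x, value) {
    x@valueKind <- value
    validObject(x)
    x
})

#' @describeIn plantedTruth truth table stored by the simulator, if any.
#' @export
setMethod("plantedTruth", "AZExperiment",
    function(x) metadata(x)$plantedTruth)

#' Sample design of an experiment
#'
#' @param x an [AZExperiment].
#' @return data.frame with one row per sample: sample_id, tissue, time_h,
#'   replicate, genotype.
#' @export
sampleDesign <- function(x) {
    stopifnot(is(x, "AZExperiment"))
    d <- as.data.frame(colData(x))
    cbind(sample_id = rownames(d), d[c("tissue", "time_h", "replicate",
                                      "genotype")],
          stringsAsFactors = FALSE)
}

#' Gene annotation of an experiment
#'
#' @param x an [AZExperiment].
#' @return data.frame with one row per gene: gene_id, length_bp, description.
#' @export
geneAnnotation <- function(x) {
    stopifnot(is(x, "AZExperiment"))
    a <- as.data.frame(rowData(x))
    cbind(gene_id = rownames(a), a, stringsAsFactors = FALSE)
}

#' @export
#' @describeIn AZExperiment compact display.
#' @param object an [AZExperiment].
setMethod("show", "AZExperiment", function(object) {
    cat(sprintf("AZExperiment [%s]: %d genes x %d samples\n",
                object@valueKind, nrow(object), ncol(object)))
    d <- colData(object)
    cat(sprintf("  tissues: %s | times (h): %s | genotypes: %s\n",
                paste(unique(d$tissue), collapse = ", "),
                paste(sort(unique(d$time_h)), collapse = ", "),
                paste(unique(d$genotype), collapse = ", ")))
    if (!is.null(metadata(object)$plantedTruth))
        cat("  planted truth: yes\n")
    invisible(NULL)
})

#' @export
#' @describeIn gateProfile display method.
#' @param object a [GateProfile].
setMethod("show", "GateProfile", function(object) {
    cat(sprintf(
        "GateProfile '%s' on %s: mean %s %g in >=1 condition; floor %g\n",
        object@name, object@valueKind, if (object@strict) ">" else ">=",
        object@threshold, object@floor))
    invisible(NULL)
})

#' @export
#' @describeIn thresholdConfig display method.
#' @param object a [ThresholdConfig].
setMethod("show", "ThresholdConfig", function(object) {
    op <- if (object@strict) ">" else ">="
    cat(sprintf(
        "ThresholdConfig: changed |log2 t/0| %s %g; AZ-specific log2 %s %g; p < %g\n",
        op, object@foldLog2, op, object@azSpecificLog2, object@pvalueMax))
    invisible(NULL)
})

#' @export
#' @describeIn categoryProfile display method.
#' @param object a [CategoryProfile].
setMethod("show", "CategoryProfile", function(object) {
    cat(sprintf("CategoryProfile: %d categories x %d samples\n",
                nrow(object@percent), ncol(object@percent)))
    for (cat_ in utils::head(rownames(object@percent), 8))
        cat(sprintf("  %s (%d genes)\n", cat_, object@counts[[cat_]]))
    if (nrow(object@percent) > 8) cat("  ...\n")
    invisible(NULL)
})

#' Percent matrix, member counts and dominant genes of a CategoryProfile
#'
#' @param x a [CategoryProfile].
#' @return \code{categoryPercent}: category-by-sample matrix of percent of
#'   transcriptome; \code{categoryCounts}: named member counts;
#'   \code{categoryDominant}: DataFrame of dominant gene and share per
#'   category and condition.
#' @export
categoryPercent <- function(x) {
    stopifnot(is(x, "CategoryProfile"))
    x@percent
}

#' @rdname categoryPercent
#' @export
categoryCounts <- function(x) {
    stopifnot(is(x, "CategoryProfile"))
    x@counts
}

#' @rdname categoryPercent
#' @export
categoryDominant <- function(x) {
    stopifnot(is(x, "CategoryProfile"))
    x@dominant
}
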