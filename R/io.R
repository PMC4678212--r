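# shared writer: tab-delimited UTF-8, header row, no quoting
.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read / write a gene-by-sample expression matrix
#'
#' Tab-delimited with a header row of sample ids and gene ids in the first
#' column. Ragged rows, non-numeric cells and duplicate gene or sample ids
#' are rejected with the offending line or id named.
#'
#' @param path file path.
#' @param valueKind what the numbers are (\code{"counts"}, \code{"rpkm"},
#'   \code{"signal"}).
#' @return \code{readExpressionMatrix}: a numeric matrix with the attribute
#'   \code{valueKind}; pair it with a design via [AZExperiment()].
#' @export
readExpressionMatrix <- function(path, valueKind = "counts") {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop("empty matrix file: ", path)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    width <- lengths(cells)
    if (any(width != width[1]))
        stop("ragged row at line ", which(width != width[1])[1], " of ", path)
    header <- cells[[1]][-1]
    if (anyDuplicated(header))
        stop("duplicated sample id: ", header[duplicated(header)][1])
    ids <- vapply(cells[-1], `[[`, "", 1L)
    if (anyDuplicated(ids)) {
        d <- which(duplicated(ids))[1]
        stop("duplicated gene id '", ids[d], "' at line ", d + 1L)
    }
    body <- lapply(seq_along(cells[-1]), function(i) {
        v <- suppressWarnings(as.numeric(cells[[i + 1L]][-1]))
        if (anyNA(v))
            stop("non-numeric cell at line ", i + 1L, " of ", path)
        v
    })
    m <- do.call(rbind, body)
    dimnames(m) <- list(ids, header)
    attr(m, "valueKind") <- valueKind
    m
}

#' @rdname readExpressionMatrix
#' @param x an [AZExperiment] or a matrix with row/column names.
#' @export
writeExpressionMatrix <- function(x, path) {
    m <- if (is(x, "AZExperiment")) assay(x) else as.matrix(x)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
    invisible(path)
}

#' Read / write a sample design table
#'
#' Columns: sample_id, tissue, time_h, replicate, genotype.
#'
#' @param path file path.
#' @return \code{readSampleDesign}: a data.frame with sample ids as rownames.
#' @export
readSampleDesign <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "tissue", "time_h", "replicate", "genotype")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("design file lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample id in design: ",
             df$sample_id[duplicated(df$sample_id)][1])
    rownames(df) <- df$sample_id
    df[c("tissue", "time_h", "replicate", "genotype")]
}

#' @rdname readSampleDesign
#' @param x an [AZExperiment] or a design data.frame with a sample_id column.
#' @export
writeSampleDesign <- function(x, path) {
    df <- if (is(x, "AZExperiment")) sampleDesign(x) else as.data.frame(x)
    .writeTsv(df, path)
    invisible(path)
}

#' Read / write a gene annotation table
#'
#' Columns: gene_id, length_bp, description.
#'
#' @param path file path.
#' @return \code{readGeneAnnotation}: data.frame with gene ids as rownames.
#' @export
readGeneAnnotation <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "length_bp", "description")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("annotation file lacks column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$gene_id))
        stop("duplicated gene id in annotation: ",
             df$gene_id[duplicated(df$gene_id)][1])
    rownames(df) <- df$gene_id
    df[c("length_bp", "description")]
}

#' @rdname readGeneAnnotation
#' @param x an [AZExperiment] or an annotation data.frame with a gene_id
#'   column.
#' @export
writeGeneAnnotation <- function(x, path) {
    df <- if (is(x, "AZExperiment")) geneAnnotation(x) else as.data.frame(x)
    .writeTsv(df, path)
    invisible(path)
}

#' Write a differential or flag table
#'
#' Serializes a \code{DataFrame} (e.g. a classified [differentialTable()])
#' with gene ids in the first column.
#'
#' @param diff a \code{DataFrame} or data.frame with gene rownames.
#' @param path file path.
#' @export
writeDifferentialTable <- function(diff, path) {
    df <- as.data.frame(diff)
    df <- data.frame(gene_id = rownames(df), df, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
    invisible(path)
}

#' Assemble an AZExperiment from matrix, design and annotation files
#'
#' @param matrixPath,designPath,annotationPath tab-delimited input files.
#' @param valueKind what the matrix values are.
#' @return an [AZExperiment].
#' @export
readAZExperiment <- function(matrixPath, designPath, annotationPath = NULL,
                             valueKind = "counts") {
    m <- readExpressionMatrix(matrixPath, valueKind)
    design <- readSampleDesign(designPath)
    extra <- setdiff(colnames(m), rownames(design))
    if (length(extra))
        stop("sample(s) in matrix absent from design: ",
             paste(extra, collapse = ", "))
    ann <- if (is.null(annotationPath)) NULL else
        readGeneAnnotation(annotationPath)
    AZExperiment(m, design[colnames(m), , drop = FALSE], ann, valueKind)
}
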