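#' Built-in and custom expression gate profiles
#'
#' Three built-ins encode the platform rules: \code{soybean_rnaseq} (mean
#' RPKM of at least 1.0 in at least one treatment, non-strict; floor 0.1),
#' \code{tomato_microarray} (mean signal > 10 in at least one time point,
#' strict; floor 1.0) and \code{arabidopsis_readcount} (> 10 reads in either
#' genotype, strict; floor 1.0). \code{custom} takes explicit values.
#'
#' @param name profile name.
#' @param threshold,strict,floor,valueKind settings for a \code{custom}
#'   profile; ignored for built-ins.
#' @return a [GateProfile-class].
#' @examples
#' gateProfile("soybean_rnaseq")
#' gateProfile("custom", threshold = 5, strict = TRUE, floor = 0.5,
#'             valueKind = "rpkm")
#' @export
gateProfile <- function(name = c("soybean_rnaseq", "tomato_microarray",
                                 "arabidopsis_readcount", "custom"),
                        threshold = NULL, strict = NULL, floor = NULL,
                        valueKind = NULL) {
    name <- match.arg(name)
    p <- switch(name,
        soybean_rnaseq = list(1.0, FALSE, 0.1, "rpkm"),
        tomato_microarray = list(10, TRUE, 1.0, "signal"),
        arabidopsis_readcount = list(10, TRUE, 1.0, "counts"),
        custom = {
            if (is.null(threshold) || is.null(strict) || is.null(floor) ||
                is.null(valueKind))
                stop("custom profiles need threshold, strict, floor ",
                     "and valueKind")
            list(threshold, strict, floor, valueKind)
        })
    new("GateProfile", name = name, threshold = p[[1]], strict = p[[2]],
        floor = p[[3]], valueKind = p[[4]])
}

#' RPKM normalization of a count matrix
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{\mathrm{RPKM}_{gs} = c_{gs} \times 10^9 / (L_g N_s)}
#' with \eqn{c_{gs}} the read count, \eqn{L_g} the transcript length in bp and
#' \eqn{N_s} the sample's library size, taken as the column sum of counts over
#' the genes in the matrix.
#'
#' @param x an [AZExperiment] with \code{valueKind = "counts"}.
#' @param lengths per-gene transcript lengths in bp; defaults to the
#'   \code{length_bp} column of the object's annotation.
#' @return an [AZExperiment] with \code{valueKind = "rpkm"}.
#' @examples
#' se <- simulateExperiment(designSpec(nGenes = 20, seed = 1))
#' rpkm <- computeRPKM(se)
#' @export
computeRPKM <- function(x, lengths = NULL) {
    stopifnot(is(x, "AZExperiment"))
    if (valueKind(x) != "counts")
        stop("computeRPKM expects a counts matrix, got '", valueKind(x), "'")
    if (is.null(lengths)) lengths <- rowData(x)$length_bp
    if (is.null(lengths)) stop("no gene lengths available")
    lengths <- as.numeric(lengths)
    bad <- which(is.na(lengths) | lengths <= 0)
    if (length(bad))
        stop("missing or non-positive length for gene(s): ",
             paste(utils::head(rownames(x)[bad], 5), collapse = ", "))
    m <- assay(x)
    libSize <- colSums(m)
    zero <- which(libSize == 0)
    if (length(zero))
        stop("zero library size in sample(s): ",
             paste(colnames(x)[zero], collapse = ", "))
    rpkm <- m * 1e9 / outer(lengths, libSize)
    out <- x
    assay(out) <- rpkm
    out@valueKind <- "rpkm"
    out
}

#' @describeIn applyFloor elementwise \code{pmax(x, floor)} on a matrix.
#' @export
setMethod("applyFloor", "matrix", function(x, floor) {
    if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
        stop("floor must be a single positive number")
    pmax(x, floor)
})

#' @describeIn applyFloor floors the assay, preserving everything else.
#' @export
setMethod("applyFloor", "AZExperiment", function(x, floor) {
    assay(x) <- applyFloor(assay(x), floor)
    x
})

#' @rdname conditionMeans
#' @export
setMethod("conditionMeans", "AZExperiment", function(x) {
    d <- colData(x)
    key <- sprintf("%s_t%g_%s", d$tissue, d$time_h, d$genotype)
    lv <- unique(key)
    m <- assay(x)
    out <- vapply(lv, function(k) rowMeans(m[, key == k, drop = FALSE]),
                  numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), lv))
    first <- match(lv, key)
    attr(out, "conditions") <- data.frame(
        condition = lv, tissue = d$tissue[first], time_h = d$time_h[first],
        genotype = d$genotype[first], stringsAsFactors = FALSE)
    out
})

#' Which genes pass the expression gate
#'
#' A gene is expressed when the mean over replicates within at least one
#' condition (tissue by time, or genotype) satisfies the profile's threshold
#' — strictly (\code{>}) or non-strictly (\code{>=}) depending on the
#' profile. The gate is applied to unfloored values; flooring follows it.
#'
#' @param x an [AZExperiment] whose \code{valueKind} matches the profile.
#' @param profile a [gateProfile()].
#' @return character vector of expressed gene ids (a subset of
#'   \code{rownames(x)}).
#' @examples
#' se <- computeRPKM(simulateExperiment(designSpec(nGenes = 50, seed = 2)))
#' expressed <- applyGate(se, gateProfile("soybean_rnaseq"))
#' @export
applyGate <- function(x, profile) {
    stopifnot(is(x, "AZExperiment"), is(profile, "GateProfile"))
    if (valueKind(x) != profile@valueKind)
        stop(sprintf("profile '%s' applies to %s values, matrix holds %s",
                     profile@name, profile@valueKind, valueKind(x)))
    cm <- conditionMeans(x)
    best <- apply(cm, 1L, max)
    pass <- if (profile@strict) best > profile@threshold
            else best >= profile@threshold
    rownames(x)[pass]
}
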