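#' Log2 ratio between two condition means
#'
#' @param means gene-by-condition matrix of floored condition means (see
#'   [conditionMeans()] and [applyFloor()]; flooring guarantees finiteness).
#' @param numerator,denominator condition ids (column names of \code{means}).
#' @return named numeric vector of per-gene log2 ratios; antisymmetric under
#'   swapping the two conditions.
#' @examples
#' m <- matrix(c(8, 1), 1, 2, dimnames = list("g1", c("a", "b")))
#' log2Ratio(m, "a", "b")  # 3
#' @export
log2Ratio <- function(means, numerator, denominator) {
    for (cond in c(numerator, denominator))
        if (!cond %in% colnames(means))
            stop("unknown condition: ", cond)
    log2(means[, numerator] / means[, denominator])
}

#' Reverse the orientation of a log2 fold-change table
#'
#' Negates every value, turning mutant/WT ratios into WT/mutant ones (or any
#' contrast into its reverse). An involution: applying it twice restores the
#' input.
#'
#' @param x numeric vector, matrix or data.frame of signed log2 values.
#' @return object of the same shape with every value negated.
#' @export
reverseContrast <- function(x) {
    if (is.data.frame(x)) {
        num <- vapply(x, is.numeric, logical(1))
        x[num] <- lapply(x[num], function(v) -v)
        x
    } else {
        -x
    }
}

#' Two-sided test of differential expression between two replicate groups
#'
#' Welch two-sample t on log2-transformed replicate values (which must be
#' positive — floor first). With fewer than two replicates in either group no
#' finite p can be computed: the function warns and returns 1 (never
#' significant). Identical groups give p = 1; degenerate zero-variance groups
#' with unequal means give the smallest positive double.
#'
#' @param a,b positive replicate values for one gene in conditions A and B.
#' @return a two-sided p-value in (0, 1].
#' @examples
#' testContrast(c(10, 10.1, 9.9), c(1000, 1010, 990))  # very small
#' @export
testContrast <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L)
        stop("empty condition in testContrast")
    if (length(a) < 2L || length(b) < 2L) {
        warning("fewer than 2 replicates in a condition; returning p = 1")
        return(1)
    }
    if (any(a <= 0) || any(b <= 0))
        stop("testContrast expects positive (floored) values")
    la <- log2(a); lb <- log2(b)
    if (stats::var(la) == 0 && stats::var(lb) == 0) {
        return(if (mean(la) == mean(lb)) 1 else .Machine$double.xmin)
    }
    stats::t.test(la, lb)$p.value
}

#' Ratio statistics for a two-tissue time course
#'
#' For every gene: the AZ/NAZ log2 ratio at each time point (AZ-specificity),
#' the time/0 h log2 ratio per tissue at each non-zero time, and a Welch-t
#' p-value per AZ time-versus-0 h contrast computed on log2 replicate values.
#' Input values must already be floored so every ratio is finite.
#'
#' @param x a floored [AZExperiment] (typically RPKM or signal, subset to
#'   expressed genes).
#' @param azTissue,nazTissue tissue labels for the specificity ratio; default
#'   to the first and second tissue in the design.
#' @return a \code{DataFrame}, one row per gene, with columns
#'   \code{log2_az_naz_t<T>}, \code{log2_t0_<tissue>_t<T>} and
#'   \code{pvalue_t<T>}; the attribute \code{metadata} records the time grid
#'   and tissue roles.
#' @examples
#' se <- computeRPKM(simulateExperiment(designSpec(nGenes = 30, seed = 5)))
#' diff <- differentialTable(applyFloor(se, 0.1))
#' @export
differentialTable <- function(x, azTissue = NULL, nazTissue = NULL) {
    stopifnot(is(x, "AZExperiment"))
    d <- colData(x)
    tissues <- unique(d$tissue)
    if (is.null(azTissue)) azTissue <- tissues[1]
    if (is.null(nazTissue)) nazTissue <- setdiff(tissues, azTissue)[1]
    if (!azTissue %in% tissues || !nazTissue %in% tissues)
        stop("azTissue/nazTissue not present in the design")
    times <- sort(unique(d$time_h))
    genotype <- unique(d$genotype)[1]
    cm <- conditionMeans(x)
    if (any(cm <= 0))
        stop("condition means must be positive; apply a floor first")
    m <- assay(x)

    cond <- function(tissue, t) sprintf("%s_t%g_%s", tissue, t, genotype)
    out <- DataFrame(row.names = rownames(x))
    for (t in times)
        out[[sprintf("log2_az_naz_t%g", t)]] <-
            log2Ratio(cm, cond(azTissue, t), cond(nazTissue, t))
    for (tissue in c(azTissue, nazTissue))
        for (t in times[-1])
            out[[sprintf("log2_t0_%s_t%g", tissue, t)]] <-
                log2Ratio(cm, cond(tissue, t), cond(tissue, 0))
    t0Cols <- d$tissue == azTissue & d$time_h == times[1]
    for (t in times[-1]) {
        tCols <- d$tissue == azTissue & d$time_h == t
        a <- m[, tCols, drop = FALSE]
        b <- m[, t0Cols, drop = FALSE]
        out[[sprintf("pvalue_t%g", t)]] <- vapply(
            seq_len(nrow(m)),
            function(i) testContrast(a[i, ], b[i, ]),
            numeric(1))
    }
    metadata(out) <- list(times = times, azTissue = azTissue,
                          nazTissue = nazTissue)
    out
}

#' Differential statistics for a two-genotype contrast
#'
#' Log2 fold change of condition means oriented numerator/denominator
#' (WT over mutant by default) and a Welch-t p-value per gene on log2
#' replicate values.
#'
#' @param x a floored [AZExperiment] in read-count mode.
#' @param numerator,denominator genotype labels; default WT over the other
#'   genotype.
#' @return \code{DataFrame} with columns \code{log2_fc} and \code{pvalue}.
#' @export
genotypeDifferential <- function(x, numerator = NULL, denominator = NULL) {
    stopifnot(is(x, "AZExperiment"))
    d <- colData(x)
    genotypes <- unique(d$genotype)
    if (length(genotypes) != 2L)
        stop("genotypeDifferential needs exactly two genotypes")
    if (is.null(numerator))
        numerator <- if ("WT" %in% genotypes) "WT" else genotypes[1]
    if (is.null(denominator)) denominator <- setdiff(genotypes, numerator)[1]
    cm <- conditionMeans(x)
    conds <- attr(cm, "conditions")
    num <- conds$condition[conds$genotype == numerator]
    den <- conds$condition[conds$genotype == denominator]
    m <- assay(x)
    a <- m[, d$genotype == numerator, drop = FALSE]
    b <- m[, d$genotype == denominator, drop = FALSE]
    out <- DataFrame(
        log2_fc = log2Ratio(cm, num, den),
        pvalue = vapply(seq_len(nrow(m)),
                        function(i) testContrast(a[i, ], b[i, ]),
                        numeric(1)),
        row.names = rownames(x))
    metadata(out) <- list(numerator = numerator, denominator = denominator)
    out
}

#' Classify genes by the fold-change and significance filter cascade
#'
#' Adds four logical flags to a [differentialTable()]:
#' \itemize{
#'   \item \code{changed_up}: the maximum AZ time/0 h log2 ratio exceeds the
#'     fold threshold (default 3, i.e. an 8-fold increase);
#'   \item \code{changed_down}: the minimum falls below its negation; when a
#'     gene qualifies for both, the larger |log2| wins and an exact tie gives
#'     neither flag (logged);
#'   \item \code{az_specific}: the maximum AZ/NAZ log2 ratio over time points
#'     exceeds the AZ-specificity threshold;
#'   \item \code{significant_changed}: changed up \emph{and} p below the
#'     ceiling (default 0.015) for at least one time contrast whose log2
#'     ratio itself exceeds the fold threshold.
#' }
#' All comparisons are strict under the default configuration, so boundary
#' values (log2 ratio exactly 3, p exactly 0.015) are excluded.
#'
#' @param diff a [differentialTable()] result.
#' @param thresholds a [thresholdConfig()].
#' @return \code{diff} with flag columns appended.
#' @export
classifyGenes <- function(diff, thresholds = thresholdConfig()) {
    stopifnot(is(thresholds, "ThresholdConfig"))
    validObject(thresholds)
    md <- metadata(diff)
    times <- md$times
    az <- md$azTissue
    if (is.null(times) || is.null(az))
        stop("diff lacks time-course metadata; build it with ",
             "differentialTable()")
    gt <- function(v, thr) if (thresholds@strict) v > thr else v >= thr
    t0Cols <- sprintf("log2_t0_%s_t%g", az, times[-1])
    azCols <- sprintf("log2_az_naz_t%g", times)
    pCols <- sprintf("pvalue_t%g", times[-1])
    t0 <- as.matrix(as.data.frame(diff[, t0Cols, drop = FALSE]))
    azm <- as.matrix(as.data.frame(diff[, azCols, drop = FALSE]))
    pm <- as.matrix(as.data.frame(diff[, pCols, drop = FALSE]))

    up <- gt(apply(t0, 1L, max), thresholds@foldLog2)
    down <- gt(-apply(t0, 1L, min), thresholds@foldLog2)
    both <- which(up & down)
    if (length(both)) {
        hi <- apply(t0[both, , drop = FALSE], 1L, max)
        lo <- -apply(t0[both, , drop = FALSE], 1L, min)
        tie <- hi == lo
        up[both] <- hi > lo
        down[both] <- lo > hi
        if (any(tie))
            message(sum(tie), " gene(s) with an exact up/down tie left ",
                    "unflagged")
    }
    sigContrast <- (pm < thresholds@pvalueMax) & gt(t0, thresholds@foldLog2)
    diff$changed_up <- unname(up)
    diff$changed_down <- unname(down)
    diff$az_specific <- unname(gt(apply(azm, 1L, max),
                                  thresholds@azSpecificLog2))
    diff$significant_changed <- unname(up & apply(sigContrast, 1L, any))
    diff
}

#' Threshold configuration constructor
#'
#' @param foldLog2 log2 fold threshold (default 3, an 8-fold change).
#' @param pvalueMax p-value ceiling (default 0.015).
#' @param azSpecificLog2 AZ-specificity log2 threshold (default 3).
#' @param strict strict (\code{>}) comparisons, the default.
#' @return a [ThresholdConfig-class].
#' @examples
#' thresholdConfig()
#' @export
thresholdConfig <- function(foldLog2 = 3, pvalueMax = 0.015,
                            azSpecificLog2 = 3, strict = TRUE) {
    new("ThresholdConfig", foldLog2 = foldLog2, pvalueMax = pvalueMax,
        azSpecificLog2 = azSpecificLog2, strict = strict)
}

#' Share of the transcriptome carried by a gene set
#'
#' The summed expression of \code{geneSet} in \code{sample}, as a percent of
#' the summed expression of all genes in the matrix (which should already be
#' restricted to expressed genes).
#'
#' @param x an [AZExperiment] or a numeric gene-by-sample matrix.
#' @param geneSet character vector of gene ids, a subset of the matrix genes.
#' @param sample sample id(s); defaults to all samples.
#' @return named numeric vector of percents in \[0, 100\], one per sample.
#' @examples
#' m <- matrix(c(50, 950), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' transcriptomeShare(m, "a", "s1")  # 5
#' @export
transcriptomeShare <- function(x, geneSet, sample = NULL) {
    m <- if (is(x, "AZExperiment")) assay(x) else as.matrix(x)
    if (is.null(sample)) sample <- colnames(m)
    if (!all(sample %in% colnames(m)))
        stop("unknown sample(s): ",
             paste(setdiff(sample, colnames(m)), collapse = ", "))
    missing <- setdiff(geneSet, rownames(m))
    if (length(missing))
        stop("gene set contains ids absent from the matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    total <- colSums(m[, sample, drop = FALSE])
    if (any(total == 0))
        stop("zero total expression in sample(s): ",
             paste(sample[total == 0], collapse = ", "))
    part <- colSums(m[geneSet, sample, drop = FALSE])
    100 * part / total
}
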