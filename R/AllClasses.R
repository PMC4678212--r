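#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom SummarizedExperiment "assay<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

.VALUE_KINDS <- c("counts", "rpkm", "signal")
.EFFECT_CLASSES <- c("az_up", "shared_up", "shared_down", "null")

#' AZExperiment: expression matrix plus sample design and gene annotation
#'
#' The central container of the package. It extends
#' \linkS4class{SummarizedExperiment}: the single assay holds a gene-by-sample
#' matrix of raw counts, RPKM or microarray signal; \code{colData} carries the
#' sample design (tissue, time in hours, replicate, genotype); \code{rowData}
#' carries the gene annotation (transcript length in bp, free-text
#' description). A \code{valueKind} marker records what the numbers are, so
#' that normalization and gating can refuse mismatched inputs.
#'
#' @slot valueKind one of \code{"counts"}, \code{"rpkm"}, \code{"signal"}.
#'
#' @seealso [AZExperiment()] for the constructor, [simulateExperiment()] for
#'   synthetic objects with planted ground truth.
#' @export
setClass("AZExperiment",
    contains = "SummarizedExperiment",
    representation(valueKind = "character")
)

setValidity("AZExperiment", function(object) {
    msg <- character()
    if (length(object@valueKind) != 1L || !object@valueKind %in% .VALUE_KINDS)
        msg <- c(msg, sprintf("valueKind must be one of %s",
                              paste(.VALUE_KINDS, collapse = ", ")))
    m <- assay(object)
    if (anyNA(m))
        msg <- c(msg, "expression values must not contain missing values")
    else if (any(m < 0))
        msg <- c(msg, "expression values must be non-negative")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    need <- c("tissue", "time_h", "replicate", "genotype")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, sprintf("sample design lacks column(s): %s",
                              paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Platform-specific expression gate profile
#'
#' Encodes the rule deciding whether a gene counts as expressed: the mean over
#' replicates must satisfy \code{threshold} in at least one condition. The
#' soybean RNA-seq gate is non-strict (mean RPKM of at least 1.0), while the
#' tomato microarray and Arabidopsis read-count gates are strict (mean signal
#' or reads greater than 10). \code{floor} is the value substituted for
#' anything smaller before ratios are taken, so no ratio ever has a zero in
#' the numerator or denominator.
#'
#' @slot name profile name.
#' @slot threshold expression threshold applied to condition means.
#' @slot strict if \code{TRUE} the gate requires \code{mean > threshold},
#'   otherwise \code{mean >= threshold}.
#' @slot floor substitution floor (must be below the threshold).
#' @slot valueKind the value kind the profile applies to.
#'
#' @seealso [gateProfile()], [applyGate()], [applyFloor()]
#' @export
setClass("GateProfile",
    representation(name = "character", threshold = "numeric",
                   strict = "logical", floor = "numeric",
                   valueKind = "character")
)

setValidity("GateProfile", function(object) {
    msg <- character()
    if (length(object@floor) != 1L || object@floor <= 0)
        msg <- c(msg, "floor must be a single positive number")
    if (length(object@threshold) != 1L || object@threshold <= 0)
        msg <- c(msg, "threshold must be a single positive number")
    if (length(object@floor) == 1L && length(object@threshold) == 1L &&
        object@floor >= object@threshold)
        msg <- c(msg, "floor must be below the expression threshold")
    if (!object@valueKind %in% .VALUE_KINDS)
        msg <- c(msg, "valueKind must be counts, rpkm or signal")
    if (length(msg)) msg else TRUE
})

#' Fold-change and significance thresholds for gene classification
#'
#' Defaults encode the filter cascade used throughout the analysis: a gene is
#' called changed when some time-to-0 h log2 ratio exceeds 3 (an 8-fold
#' change), AZ-specific when some AZ/NAZ log2 ratio exceeds 3, and
#' significantly changed when it is changed up with p < 0.015 for a contrast
#' whose log2 ratio exceeds 3. All comparisons are strict by default, so exact
#' boundary values (log2 ratio of 3.0, p of 0.015) are excluded.
#'
#' @slot foldLog2 log2 fold threshold for changed-up/down calls.
#' @slot pvalueMax p-value ceiling for the significance filter.
#' @slot azSpecificLog2 log2 AZ/NAZ threshold for AZ-specificity.
#' @slot strict strict (\code{>}) versus non-strict (\code{>=}) comparison.
#'
#' @seealso [thresholdConfig()], [classifyGenes()]
#' @export
setClass("ThresholdConfig",
    representation(foldLog2 = "numeric", pvalueMax = "numeric",
                   azSpecificLog2 = "numeric", strict = "logical")
)

setValidity("ThresholdConfig", function(object) {
    msg <- character()
    if (object@foldLog2 <= 0) msg <- c(msg, "foldLog2 must be positive")
    if (object@azSpecificLog2 <= 0)
        msg <- c(msg, "azSpecificLog2 must be positive")
    if (object@pvalueMax <= 0 || object@pvalueMax >= 1)
        msg <- c(msg, "pvalueMax must lie strictly between 0 and 1")
    if (length(msg)) msg else TRUE
})

#' Experiment layout for the synthetic-data generator
#'
#' Describes the shape of a simulated experiment: two tissues sampled over an
#' ethylene (or auxin-depletion) time course with replicates, or a two-genotype
#' single-time contrast in read-count mode.
#'
#' @slot nGenes number of genes.
#' @slot tissues ordered tissue labels (abscission zone first).
#' @slot timepointsH sampling times in hours; strictly increasing, starting
#'   at 0.
#' @slot nReplicates replicates per condition.
#' @slot platform \code{"rnaseq"}, \code{"microarray"} or \code{"readcount"}.
#' @slot genotypes genotype labels; two in read-count mode, one otherwise.
#' @slot seed integer seed making the simulation reproducible.
#'
#' @seealso [designSpec()], [simulateExperiment()]
#' @export
setClass("DesignSpec",
    representation(nGenes = "integer", tissues = "character",
                   timepointsH = "numeric", nReplicates = "integer",
                   platform = "character", genotypes = "character",
                   seed = "integer")
)

setValidity("DesignSpec", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (!object@platform %in% c("rnaseq", "microarray", "readcount"))
        msg <- c(msg, "platform must be rnaseq, microarray or readcount")
    tp <- object@timepointsH
    if (object@platform == "readcount") {
        if (length(tp) > 1L || (length(tp) == 1L && tp != 0))
            msg <- c(msg, "readcount mode has no time axis")
        if (length(object@genotypes) != 2L)
            msg <- c(msg, "readcount mode requires exactly two genotypes")
        if (length(object@tissues) != 1L)
            msg <- c(msg, "readcount mode uses a single tissue")
    } else {
        if (length(tp) < 2L || tp[1] != 0 || any(diff(tp) <= 0))
            msg <- c(msg,
                "timepointsH must be strictly increasing and start at 0")
        if (length(object@tissues) != 2L)
            msg <- c(msg, "time-course modes require exactly two tissues")
    }
    if (length(msg)) msg else TRUE
})

#' Effect structure for the synthetic-data generator
#'
#' Splits genes into four classes — AZ-specifically up-regulated, commonly
#' up-regulated, commonly down-regulated and unchanged — and sets the planted
#' fold range, noise model and baseline abundance distribution.
#'
#' @slot classFractions named proportions over the four effect classes,
#'   summing to 1.
#' @slot foldRangeLog2 range of planted |log2 fold|; the lower bound exceeds 3
#'   so planted genes clear the 8-fold selection threshold by construction.
#' @slot onsetTimeH time at which planted effects switch on.
#' @slot baselineLogMean,baselineLogSd log-normal baseline abundance of null
#'   genes, on the platform's analysis scale (RPKM or signal).
#' @slot upBaseline,downBaseline log-normal (meanlog, sdlog) baseline strata
#'   for the up-regulated and down-regulated classes: induced genes start
#'   from a small share of the transcriptome, declining genes from an
#'   abundant one, which keeps planted relative fold changes observable
#'   through the per-sample RPKM denominator.
#' @slot dispersion negative-binomial dispersion for count modes.
#' @slot cvNoise multiplicative (log-normal) noise CV for microarray signals.
#' @slot nearGateFraction fraction of null genes drawn with baseline near the
#'   expression gate, exercising the gate boundary.
#' @slot libSizeMean,libSizeCV mean and coefficient of variation of simulated
#'   per-sample library sizes.
#'
#' @seealso [effectSpec()], [simulateExperiment()]
#' @export
setClass("EffectSpec",
    representation(classFractions = "numeric", foldRangeLog2 = "numeric",
                   onsetTimeH = "numeric", baselineLogMean = "numeric",
                   baselineLogSd = "numeric", upBaseline = "numeric",
                   downBaseline = "numeric", dispersion = "numeric",
                   cvNoise = "numeric", nearGateFraction = "numeric",
                   libSizeMean = "numeric", libSizeCV = "numeric")
)

setValidity("EffectSpec", function(object) {
    msg <- character()
    f <- object@classFractions
    if (!identical(sort(names(f)), sort(.EFFECT_CLASSES)))
        msg <- c(msg, sprintf("classFractions must be named %s",
                              paste(.EFFECT_CLASSES, collapse = ", ")))
    if (any(f < 0)) msg <- c(msg, "classFractions must be non-negative")
    if (abs(sum(f) - 1) > 1e-6) msg <- c(msg, "classFractions must sum to 1")
    fr <- object@foldRangeLog2
    if (length(fr) != 2L || fr[1] > fr[2])
        msg <- c(msg, "foldRangeLog2 must be an interval c(lo, hi)")
    else if (fr[1] <= 3)
        msg <- c(msg, "foldRangeLog2 lower bound must exceed 3")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
    if (length(object@upBaseline) != 2L || length(object@downBaseline) != 2L)
        msg <- c(msg, "upBaseline/downBaseline must be (meanlog, sdlog)")
    if (object@cvNoise < 0) msg <- c(msg, "cvNoise must be non-negative")
    if (object@nearGateFraction < 0 || object@nearGateFraction > 1)
        msg <- c(msg, "nearGateFraction must lie in [0, 1]")
    if (object@libSizeMean <= 0) msg <- c(msg, "libSizeMean must be positive")
    if (object@libSizeCV < 0) msg <- c(msg, "libSizeCV must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Per-category expression profile
#'
#' Aggregates a category-to-gene mapping over an expression matrix: the
#' percent of total expressed-transcriptome signal per category and sample,
#' member counts, and the dominant gene (largest share of the category's
#' signal) per category and condition.
#'
#' @slot percent category-by-sample matrix of transcriptome shares, in
#'   percent.
#' @slot counts named integer vector of member gene counts.
#' @slot dominant \code{DataFrame} with columns category, condition, gene and
#'   share.
#'
#' @seealso [categoryProfile()], [dominantGeneShare()]
#' @export
setClass("CategoryProfile",
    representation(percent = "matrix", counts = "integer",
                   dominant = "DataFrame")
)

setValidity("CategoryProfile", function(object) {
    msg <- character()
    p <- object@percent
    if (length(p) && (any(p < -1e-9) || any(p > 100 + 1e-9)))
        msg <- c(msg, "percents must lie in [0, 100]")
    if (!identical(rownames(p), names(object@counts)))
        msg <- c(msg, "percent rownames must match counts names")
    sh <- object@dominant$share
    if (length(sh) && (any(sh <= 0) || any(sh > 1 + 1e-12)))
        msg <- c(msg, "dominant shares must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})
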