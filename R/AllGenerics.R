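#' What kind of values an expression matrix holds
#'
#' @param x an [AZExperiment].
#' @param value one of \code{"counts"}, \code{"rpkm"}, \code{"signal"}.
#' @return the value-kind marker (getter) or the modified object (setter).
#' @examples
#' se <- simulateExperiment(designSpec(nGenes = 5, seed = 1))
#' valueKind(se)
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname valueKind
#' @export
setGeneric("valueKind<-", function(x, value) standardGeneric("valueKind<-"))

#' Planted ground truth of a synthetic experiment
#'
#' @param x an [AZExperiment] produced by [simulateExperiment()].
#' @return a \code{DataFrame} with one row per gene: effect \code{class},
#'   \code{true_log2_fold} (0 for null genes) and \code{length_bp}, or
#'   \code{NULL} when the object carries no truth.
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' Floor substitution
#'
#' Replaces every value below \code{floor} with \code{floor}, so downstream
#' ratios never divide by, or take the log of, zero. Idempotent and monotone.
#'
#' @param x a numeric matrix or an [AZExperiment].
#' @param floor positive substitution floor (0.1 for soybean RPKM, 1.0 for
#'   tomato signal and Arabidopsis reads).
#' @return an object of the same class with all values \code{>= floor}.
#' @examples
#' applyFloor(matrix(c(0.05, 2), 1), 0.1)
#' @export
setGeneric("applyFloor", function(x, floor) standardGeneric("applyFloor"))

#' Mean expression per experimental condition
#'
#' Averages replicates within each (tissue, time, genotype) condition — the
#' analysis unit for every ratio downstream.
#'
#' @param x an [AZExperiment].
#' @return numeric matrix, genes by conditions; column names are condition
#'   ids of the form \code{tissue_t<time>_<genotype>} and the attribute
#'   \code{"conditions"} holds the per-column design.
#' @export
setGeneric("conditionMeans", function(x) standardGeneric("conditionMeans"))
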