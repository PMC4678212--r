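#' Describe the layout of a simulated experiment
#'
#' Defaults reproduce the soybean explant design: abscission zone (AZ) and
#' petiole (NAZ) tissue collected at 0, 12, 24, 48 and 72 h of ethylene
#' exposure with three independent replicates. \code{platform = "readcount"}
#' switches to the two-genotype receptacle contrast (WT versus a
#' non-abscising \emph{hae-hsl2}-like mutant) with no time axis.
#'
#' @param nGenes number of genes to simulate.
#' @param tissues two ordered tissue labels, abscission zone first.
#' @param timepointsH strictly increasing times in hours, starting at 0.
#' @param nReplicates replicates per condition.
#' @param platform \code{"rnaseq"} (counts, soybean-like), \code{"microarray"}
#'   (signal, tomato-like) or \code{"readcount"} (counts, Arabidopsis-like
#'   genotype contrast).
#' @param genotypes genotype labels; exactly two in read-count mode.
#' @param seed integer seed.
#' @return a validated [DesignSpec-class] object.
#' @examples
#' designSpec(nGenes = 100, seed = 7)
#' designSpec(nGenes = 100, platform = "readcount", seed = 7)
#' @export
designSpec <- function(nGenes = 2000L,
                       tissues = c("AZ", "NAZ"),
                       timepointsH = c(0, 12, 24, 48, 72),
                       nReplicates = 3L,
                       platform = c("rnaseq", "microarray", "readcount"),
                       genotypes = NULL,
                       seed = 1L) {
    platform <- match.arg(platform)
    if (platform == "readcount") {
        if (is.null(genotypes)) genotypes <- c("WT", "hae-hsl2")
        if (missing(tissues)) tissues <- "receptacle"
        if (missing(timepointsH)) timepointsH <- 0
    } else {
        if (is.null(genotypes)) genotypes <- "WT"
    }
    new("DesignSpec", nGenes = as.integer(nGenes), tissues = tissues,
        timepointsH = as.numeric(timepointsH),
        nReplicates = as.integer(nReplicates), platform = platform,
        genotypes = genotypes, seed = as.integer(seed))
}

#' Describe planted effects and noise for a simulated experiment
#'
#' Genes fall into four classes: \code{az_up} (up-regulated only in the AZ, or
#' only in WT in read-count mode), \code{shared_up} and \code{shared_down}
#' (changed in both tissues), and \code{null}. Effects multiply the mean as a
#' step starting at \code{onsetTimeH}. Planted |log2 fold| values are drawn
#' uniformly from \code{foldRangeLog2}, whose lower bound exceeds 3 so every
#' planted gene clears the 8-fold selection threshold by construction.
#'
#' @param classFractions named proportions over az_up, shared_up, shared_down
#'   and null; must sum to 1.
#' @param foldRangeLog2 interval of true |log2 fold| for non-null genes.
#' @param onsetTimeH hour at which planted effects switch on.
#' @param baselineLogMean,baselineLogSd log-normal parameters of the null
#'   genes' baseline abundance on the platform's analysis scale (RPKM for
#'   RNA-seq).
#' @param upBaseline,downBaseline (meanlog, sdlog) of the baseline strata for
#'   the up- and down-regulated classes. Induced abscission genes start near
#'   zero and declining ones (cuticle/wall synthesis machinery) start
#'   abundant; beyond realism, a small initial mass share of the induced set
#'   is what makes 16-64 fold relative increases representable at all in a
#'   closed (per-sample-normalized) transcriptome.
#' @param dispersion negative-binomial dispersion of simulated counts; the
#'   default 0.02 reflects replicates that each pool tissue from dozens of
#'   explants, which averages biological variability down.
#' @param cvNoise coefficient of variation of multiplicative log-normal noise
#'   on microarray signals.
#' @param nearGateFraction fraction of null genes with baseline placed near
#'   the expression-gate threshold, exercising the gate boundary.
#' @param libSizeMean,libSizeCV mean and CV of per-sample library sizes
#'   (drawn log-normally, so RPKM's per-sample denominator varies).
#' @return a validated [EffectSpec-class] object.
#' @examples
#' effectSpec()
#' @export
effectSpec <- function(classFractions = c(az_up = 0.02, shared_up = 0.03,
                                          shared_down = 0.30, null = 0.65),
                       foldRangeLog2 = c(3.5, 6),
                       onsetTimeH = 24,
                       baselineLogMean = 0,
                       baselineLogSd = 2,
                       upBaseline = c(log(2), 1),
                       downBaseline = c(1, 1.5),
                       dispersion = 0.02,
                       cvNoise = 0.25,
                       nearGateFraction = 0.1,
                       libSizeMean = 4e6,
                       libSizeCV = 0.2) {
    new("EffectSpec", classFractions = classFractions,
        foldRangeLog2 = as.numeric(foldRangeLog2),
        onsetTimeH = as.numeric(onsetTimeH),
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        upBaseline = as.numeric(upBaseline),
        downBaseline = as.numeric(downBaseline),
        dispersion = dispersion, cvNoise = cvNoise,
        nearGateFraction = nearGateFraction,
        libSizeMean = libSizeMean, libSizeCV = libSizeCV)
}

# annotation strings drawn for simulated genes; keyword-rich entries exercise
# the category engine (incl. the GH9A1/KORRIGAN reassignment)
.DESCRIPTION_POOL <- c(
    "cellulase (glycoside hydrolase family 9) B3",
    "endo-1,4-beta-glucanase precursor",
    "glycoside hydrolase 9A1 (KORRIGAN)",
    "cellulose synthase A catalytic subunit",
    "polygalacturonase, abscission-related",
    "pectate lyase family protein",
    "alpha-expansin 1",
    "beta-expansin precursor",
    "xyloglucan endotransglucosylase/hydrolase 22",
    "thaumatin-like pathogenesis-related protein",
    "basic chitinase class I",
    "beta-1,3-glucanase 2",
    "kunitz trypsin inhibitor 1",
    "photoassimilate-responsive protein PAR1 precursor",
    "GDSL-like lipase/acylhydrolase",
    "CER4 jojoba acyl CoA reductase, wax synthesis",
    "non-specific lipid transfer protein LTP",
    "suberin biosynthesis cytochrome P450",
    "peroxidase 52 precursor",
    "laccase-like multicopper oxidase",
    "callose synthase 7",
    "extensin proline-rich cell wall protein",
    "arabinogalactan protein AGP",
    "1-aminocyclopropane-1-carboxylate synthase (ACS)",
    "ACC oxidase (ACO), ethylene biosynthesis",
    "auxin efflux carrier PIN-formed 3",
    "indole-3-acetic acid-amido synthetase GH3",
    "SAUR-like auxin-responsive protein",
    "AUX/IAA transcriptional repressor",
    "hypothetical protein",
    "unknown protein",
    "protein kinase family protein",
    "40S ribosomal protein",
    "WD-40 repeat protein",
    "mitochondrial carrier protein"
)

# exact per-class gene counts from fractions (largest-remainder rounding)
.classCounts <- function(fractions, n) {
    raw <- fractions * n
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' Simulate a two-tissue time-course or two-genotype expression experiment
#'
#' Generates counts (negative binomial on a log-normal baseline, RNA-seq and
#' read-count modes) or signal intensities (log-normal multiplicative noise,
#' microarray mode) with planted effect classes, realistic per-sample library
#' sizes, gene lengths drawn uniformly on 500–5000 bp, and keyword-bearing
#' gene descriptions for the category engine. The planted truth travels with
#' the object (see [plantedTruth()]).
#'
#' In count modes the expected count of gene \eqn{g} in sample \eqn{s} is
#' \deqn{\mu_{gs} = b_g \, m_{gs} \, L_g \, N_s / 10^9,}
#' where \eqn{b_g} is the baseline on the RPKM scale, \eqn{m_{gs}} the planted
#' fold multiplier (a step at the onset time, AZ-only for \code{az_up}),
#' \eqn{L_g} the gene length in bp and \eqn{N_s} the library size — so RPKM
#' computed from the simulated counts recovers \eqn{b_g m_{gs}} in
#' expectation.
#'
#' @param design a [designSpec()].
#' @param effects an [effectSpec()].
#' @return an [AZExperiment] with \code{valueKind} \code{"counts"} or
#'   \code{"signal"}; \code{rowData} holds gene length and description,
#'   \code{metadata(x)$plantedTruth} the truth table.
#' @examples
#' se <- simulateExperiment(designSpec(nGenes = 50, seed = 3))
#' table(plantedTruth(se)$class)
#' @export
simulateExperiment <- function(design, effects = effectSpec()) {
    stopifnot(is(design, "DesignSpec"), is(effects, "EffectSpec"))
    validObject(design); validObject(effects)
    set.seed(design@seed)
    n <- design@nGenes
    geneIds <- sprintf("gene%05d", seq_len(n))

    frac <- effects@classFractions[.EFFECT_CLASSES]
    counts <- .classCounts(frac, n)
    classes <- sample(rep(.EFFECT_CLASSES, counts))
    sign <- ifelse(classes == "shared_down", -1, 1)
    mag <- stats::runif(n, effects@foldRangeLog2[1], effects@foldRangeLog2[2])
    trueFold <- ifelse(classes == "null", 0, sign * mag)

    lengths <- as.integer(round(stats::runif(n, 500, 5000)))
    # class-stratified baselines: null genes span the global distribution,
    # induced classes start low and the declining class starts abundant --
    # the composition structure under which relative (RPKM-scale) fold
    # changes of the planted size are observable
    baseline <- stats::rlnorm(n, effects@baselineLogMean,
                              effects@baselineLogSd)
    isUp <- classes %in% c("az_up", "shared_up")
    if (any(isUp))
        baseline[isUp] <- stats::rlnorm(sum(isUp), effects@upBaseline[1],
                                        effects@upBaseline[2])
    isDown <- classes == "shared_down"
    if (any(isDown))
        baseline[isDown] <- stats::rlnorm(sum(isDown),
                                          effects@downBaseline[1],
                                          effects@downBaseline[2])
    # the scale on which 'expressed' is decided differs by platform
    gate <- if (design@platform == "rnaseq") 1.0 else 10
    isNull <- classes == "null"
    nNear <- round(effects@nearGateFraction * sum(isNull))
    if (nNear > 0) {
        near <- sample(which(isNull), nNear)
        baseline[near] <- stats::runif(nNear, 0.5 * gate, 2 * gate)
    }
    descriptions <- sample(.DESCRIPTION_POOL, n, replace = TRUE)

    if (design@platform == "readcount") {
        grid <- expand.grid(replicate = seq_len(design@nReplicates),
                            genotype = design@genotypes,
                            stringsAsFactors = FALSE)
        grid$tissue <- design@tissues[1]
        grid$time_h <- 0
        sampleIds <- sprintf("%s_r%d", grid$genotype, grid$replicate)
    } else {
        grid <- expand.grid(replicate = seq_len(design@nReplicates),
                            time_h = design@timepointsH,
                            tissue = design@tissues,
                            stringsAsFactors = FALSE)
        grid$genotype <- design@genotypes[1]
        sampleIds <- sprintf("%s_t%g_r%d", grid$tissue, grid$time_h,
                             grid$replicate)
    }
    nS <- nrow(grid)
    sdlogLib <- sqrt(log(1 + effects@libSizeCV^2))
    libSizes <- stats::rlnorm(nS, log(effects@libSizeMean) - sdlogLib^2 / 2,
                              sdlogLib)

    azTissue <- design@tissues[1]
    wtGenotype <- design@genotypes[1]
    mat <- matrix(0, n, nS, dimnames = list(geneIds, sampleIds))
    for (s in seq_len(nS)) {
        if (design@platform == "readcount") {
            # in the genotype contrast all planted effects act in WT only:
            # the mutant is the non-abscising reference state
            on <- classes != "null" & grid$genotype[s] == wtGenotype
        } else {
            on <- classes != "null" & grid$time_h[s] >= effects@onsetTimeH &
                (classes != "az_up" | grid$tissue[s] == azTissue)
        }
        mult <- ifelse(on, 2^trueFold, 1)
        if (design@platform == "microarray") {
            sdlog <- sqrt(log(1 + effects@cvNoise^2))
            noise <- if (effects@cvNoise > 0)
                stats::rlnorm(n, -sdlog^2 / 2, sdlog) else 1
            mat[, s] <- baseline * mult * noise
        } else {
            mu <- baseline * mult * lengths * libSizes[s] / 1e9
            mat[, s] <- stats::rnbinom(n, mu = mu,
                                       size = 1 / effects@dispersion)
        }
    }

    truth <- DataFrame(class = classes, true_log2_fold = trueFold,
                       length_bp = lengths, row.names = geneIds)
    ann <- data.frame(length_bp = lengths, description = descriptions,
                      row.names = geneIds, stringsAsFactors = FALSE)
    kind <- if (design@platform == "microarray") "signal" else "counts"
    se <- AZExperiment(mat, grid[c("tissue", "time_h", "replicate",
                                   "genotype")],
                       ann, valueKind = kind)
    metadata(se)$plantedTruth <- truth
    metadata(se)$design <- design
    metadata(se)$effects <- effects
    se
}

#' Write / read a planted-truth table
#'
#' Tab-delimited, one row per gene: gene_id, class, true_log2_fold,
#' length_bp. Round-trips losslessly.
#'
#' @param truth a truth \code{DataFrame} as returned by [plantedTruth()].
#' @param path file path.
#' @return \code{writeTruth} returns \code{path} invisibly; \code{readTruth}
#'   returns the truth \code{DataFrame}.
#' @export
writeTruth <- function(truth, path) {
    df <- data.frame(gene_id = rownames(truth),
                     class = truth$class,
                     true_log2_fold = truth$true_log2_fold,
                     length_bp = truth$length_bp,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "class", "true_log2_fold", "length_bp")
    if (!all(need %in% colnames(df)))
        stop("truth file lacks column(s): ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
    DataFrame(class = df$class, true_log2_fold = df$true_log2_fold,
              length_bp = as.integer(df$length_bp), row.names = df$gene_id)
}
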