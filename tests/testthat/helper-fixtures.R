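# small builders and independent oracles shared across the suite

suppressPackageStartupMessages(library(SummarizedExperiment))

# hand-built AZExperiment: values is a genes x samples matrix; design derived
# from sample ids of the form <tissue>_t<time>_r<rep>
toyExperiment <- function(values, valueKind = "rpkm", lengths = NULL) {
    ids <- colnames(values)
    parts <- do.call(rbind, strsplit(ids, "_", fixed = TRUE))
    design <- data.frame(
        tissue = parts[, 1],
        time_h = as.numeric(sub("^t", "", parts[, 2])),
        replicate = as.integer(sub("^r", "", parts[, 3])),
        genotype = "WT", row.names = ids)
    ann <- data.frame(
        length_bp = if (is.null(lengths)) rep(1000L, nrow(values)) else
            lengths,
        description = "", row.names = rownames(values))
    AZExperiment(values, design, ann, valueKind)
}

# straight-loop RPKM oracle: the formula applied one cell at a time
oracleRPKM <- function(counts, lengths) {
    out <- counts * NA_real_
    for (s in seq_len(ncol(counts))) {
        lib <- sum(counts[, s])
        for (g in seq_len(nrow(counts)))
            out[g, s] <- counts[g, s] * 1e9 / (lengths[g] * lib)
    }
    out
}

# straight-loop implementation of the written classification rules,
# independent of classifyGenes(): one gene at a time, explicit branches
oracleClassify <- function(t0, azm, pm, foldLog2 = 3, pvalueMax = 0.015,
                           azLog2 = 3) {
    n <- nrow(t0)
    res <- data.frame(changed_up = logical(n), changed_down = logical(n),
                      az_specific = logical(n),
                      significant_changed = logical(n))
    for (g in seq_len(n)) {
        hi <- max(t0[g, ]); lo <- min(t0[g, ])
        up <- hi > foldLog2
        down <- lo < -foldLog2
        if (up && down) {
            if (hi > -lo) down <- FALSE
            else if (-lo > hi) up <- FALSE
            else { up <- FALSE; down <- FALSE }
        }
        sig <- FALSE
        if (up)
            for (j in seq_len(ncol(t0)))
                if (t0[g, j] > foldLog2 && pm[g, j] < pvalueMax)
                    sig <- TRUE
        res$changed_up[g] <- up
        res$changed_down[g] <- down
        res$az_specific[g] <- max(azm[g, ]) > azLog2
        res$significant_changed[g] <- sig
    }
    res
}

# random classified-table fixture on the differentialTable() column layout;
# boundary values (log2 exactly 3, p exactly 0.015) planted with probability
# boundaryProb per cell
randomDiffFixture <- function(nGenes, times = c(0, 12, 24, 48, 72),
                              boundaryProb = 0.05) {
    nt <- length(times) - 1L
    t0 <- matrix(stats::runif(nGenes * nt, -6, 6), nGenes)
    azm <- matrix(stats::runif(nGenes * (nt + 1L), -6, 6), nGenes)
    pm <- matrix(stats::runif(nGenes * nt), nGenes)
    t0[stats::runif(length(t0)) < boundaryProb] <- 3
    azm[stats::runif(length(azm)) < boundaryProb] <- 3
    pm[stats::runif(length(pm)) < boundaryProb] <- 0.015
    ids <- sprintf("g%03d", seq_len(nGenes))
    diff <- S4Vectors::DataFrame(row.names = ids)
    for (j in seq_along(times))
        diff[[sprintf("log2_az_naz_t%g", times[j])]] <- azm[, j]
    for (tissue in c("AZ", "NAZ"))
        for (j in seq_len(nt))
            diff[[sprintf("log2_t0_%s_t%g", tissue, times[j + 1L])]] <-
                if (tissue == "AZ") t0[, j] else stats::runif(nGenes, -6, 6)
    for (j in seq_len(nt))
        diff[[sprintf("pvalue_t%g", times[j + 1L])]] <- pm[, j]
    S4Vectors::metadata(diff) <- list(times = times, azTissue = "AZ",
                                      nazTissue = "NAZ")
    list(diff = diff, t0 = t0, azm = azm, pm = pm)
}

# exact permutation p-value for a 2-group comparison on the log2 scale:
# statistic |difference of group means|, full enumeration of relabelings,
# p = share of non-identity relabelings at least as extreme as observed.
# Excluding the identity makes the smallest attainable p with 4+4
# replicates 1/69, so a decision at alpha = 0.015 is attainable at all.
permutationP <- function(a, b) {
    la <- log2(a); lb <- log2(b)
    pooled <- c(la, lb)
    n <- length(la)
    obs <- abs(mean(la) - mean(lb))
    splits <- utils::combn(length(pooled), n)
    stats <- apply(splits, 2L, function(idx)
        abs(mean(pooled[idx]) - mean(pooled[-idx])))
    (sum(stats >= obs - 1e-12) - 1) / (length(stats) - 1)
}

# 50-gene annotation fixture with hand-assigned expected categories for the
# shipped default rules (see inst/extdata/default_categories.yaml)
handLabeledAnnotations <- function() {
    entries <- list(
        list("cellulase (glycoside hydrolase family 9) B3", "cellulases"),
        list("endo-1,4-beta-glucanase precursor", "cellulases"),
        list("glycoside hydrolase 9 endoglucanase", "cellulases"),
        list("glycoside hydrolase 9A1 (KORRIGAN)", "cellulose_biosynthesis"),
        list("KORRIGAN-like cellulase", "cellulose_biosynthesis"),
        list("cellulose synthase A catalytic subunit",
             "cellulose_biosynthesis"),
        list("cellulose synthase (endoglucanase-like)",
             "cellulose_biosynthesis"),
        list("CESA8 cellulose synthase", "cellulose_biosynthesis"),
        list("polygalacturonase, abscission-related", "polygalacturonases"),
        list("pectate lyase family protein", "polygalacturonases"),
        list("pectin lyase-like superfamily", "polygalacturonases"),
        list("pectinase precursor", "polygalacturonases"),
        list("alpha-expansin 1", c("expansins", "expansins_alpha")),
        list("beta-expansin precursor", c("expansins", "expansins_beta")),
        list("expansin A4", c("expansins", "expansins_alpha")),
        list("expansin-like protein", "expansins"),
        list("xyloglucan endotransglucosylase/hydrolase 22", "xth"),
        list("xyloglucan endotransglycosylase 6", "xth"),
        list("thaumatin-like pathogenesis-related protein", "pr_genes"),
        list("basic chitinase class I", "pr_genes"),
        list("beta-1,3-glucanase 2", "pr_genes"),
        list("kunitz trypsin inhibitor 1", "pr_genes"),
        list("pathogenesis-related protein 10", "pr_genes"),
        list("photoassimilate-responsive protein PAR1 precursor", "par1"),
        list("GDSL-like lipase/acylhydrolase", "wax_suberin"),
        list("CER4 jojoba acyl CoA reductase, wax synthesis", "wax_suberin"),
        list("non-specific lipid transfer protein LTP", "wax_suberin"),
        list("suberin biosynthesis cytochrome P450", "wax_suberin"),
        list("fatty acid elongase", "wax_suberin"),
        list("wax ester synthase", "wax_suberin"),
        list("peroxidase 52 precursor", "peroxidase_laccase"),
        list("laccase-like multicopper oxidase", "peroxidase_laccase"),
        list("anionic peroxidase swpb3", "peroxidase_laccase"),
        list("callose synthase 7", "callose_synthase"),
        list("extensin proline-rich cell wall protein", "wall_proteins"),
        list("arabinogalactan protein AGP17", "wall_proteins"),
        list("hydroxyproline-rich glycoprotein", "wall_proteins"),
        list("1-aminocyclopropane-1-carboxylate synthase (ACS)",
             "ethylene_synthesis"),
        list("ACC oxidase (ACO), ethylene biosynthesis",
             "ethylene_synthesis"),
        list("auxin efflux carrier PIN-formed 3", "auxin"),
        list("indole-3-acetic acid-amido synthetase GH3.6", "auxin"),
        list("SAUR-like auxin-responsive protein", "auxin"),
        list("AUX/IAA transcriptional repressor", "auxin"),
        list("auxin-responsive family protein", "auxin"),
        list("hypothetical protein", character()),
        list("", character()),
        list("40S ribosomal protein S4", character()),
        list("WD-40 repeat protein", character()),
        list("protein kinase family protein", character()),
        list("mitochondrial carrier protein", character())
    )
    ids <- sprintf("fix%02d", seq_along(entries))
    ann <- data.frame(
        gene_id = ids,
        description = vapply(entries, `[[`, "", 1L),
        stringsAsFactors = FALSE)
    expected <- stats::setNames(lapply(entries, `[[`, 2L), ids)
    list(annotations = ann, expected = expected)
}

# recovery of planted truth under the acceptance study conditions
recoveryStats <- function(seed, nGenes = 2000) {
    se <- simulateExperiment(
        designSpec(nGenes = nGenes, seed = seed),
        effectSpec(foldRangeLog2 = c(4, 6)))
    gp <- gateProfile("soybean_rnaseq")
    rpkm <- computeRPKM(se)
    fl <- applyFloor(rpkm[applyGate(rpkm, gp), ], gp@floor)
    d <- classifyGenes(differentialTable(fl))
    tr <- plantedTruth(se)
    sig <- rownames(d)[d$significant_changed]
    azs <- rownames(d)[d$az_specific]
    gene <- function(cls) rownames(tr)[tr$class %in% cls]
    c(sensitivity = mean(gene(c("az_up", "shared_up")) %in% sig),
      null_fpr = mean(gene("null") %in% sig),
      az_sensitivity = mean(gene("az_up") %in% azs),
      shared_up_leak = mean(gene("shared_up") %in% azs))
}
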