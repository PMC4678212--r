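test_that("a fixed seed reproduces the experiment bit-for-bit", {
    d <- designSpec(nGenes = 80, seed = 7)
    a <- simulateExperiment(d)
    b <- simulateExperiment(d)
    expect_identical(assay(a), assay(b))
    expect_identical(plantedTruth(a), plantedTruth(b))
    expect_false(identical(assay(a),
                           assay(simulateExperiment(
                               designSpec(nGenes = 80, seed = 8)))))
})

test_that("design and effect specs reject invalid configurations", {
    expect_error(designSpec(nGenes = 10, platform = "readcount",
                            timepointsH = c(0, 12)), "time axis")
    expect_error(designSpec(nGenes = 10, platform = "readcount",
                            genotypes = "WT"), "two genotypes")
    expect_error(designSpec(nGenes = 10, timepointsH = c(12, 24)),
                 "start at 0")
    expect_error(effectSpec(classFractions = c(az_up = 0.5, shared_up = 0.2,
                                               shared_down = 0.2,
                                               null = 0.2)), "sum to 1")
    expect_error(effectSpec(foldRangeLog2 = c(2, 5)), "exceed 3")
    expect_error(effectSpec(dispersion = 0), "positive")
})

test_that("planted truth is exclusive and consistent with effect classes", {
    se <- simulateExperiment(designSpec(nGenes = 500, seed = 11))
    tr <- plantedTruth(se)
    expect_equal(nrow(tr), 500)
    expect_true(all(tr$class %in% c("az_up", "shared_up", "shared_down",
                                    "null")))
    expect_identical(tr$class == "null", tr$true_log2_fold == 0)
    expect_true(all(tr$true_log2_fold[tr$class == "shared_down"] < 0))
    expect_true(all(tr$true_log2_fold[tr$class %in%
                                      c("az_up", "shared_up")] > 0))
    # class fractions realized exactly (largest-remainder rounding)
    expect_equal(unname(table(tr$class)["null"]), 325, ignore_attr = TRUE)
    expect_identical(tr$length_bp, rowData(se)$length_bp)
})

test_that("per-sample library sizes vary across samples", {
    se <- simulateExperiment(designSpec(nGenes = 400, seed = 3))
    libs <- colSums(assay(se))
    expect_gt(stats::sd(libs) / mean(libs), 0.05)
})

test_that("planted folds are recovered by condition means at high replication", {
    # direct simulation check of mean recovery: many replicates, low noise
    se <- simulateExperiment(
        designSpec(nGenes = 300, timepointsH = c(0, 24), nReplicates = 50,
                   seed = 19),
        effectSpec(classFractions = c(az_up = 0.1, shared_up = 0,
                                      shared_down = 0, null = 0.9),
                   foldRangeLog2 = c(4, 5), dispersion = 0.005))
    cm <- conditionMeans(se)
    tr <- plantedTruth(se)
    azUp <- rownames(tr)[tr$class == "az_up"]
    # raw-count condition means compare AZ to NAZ at 24 h: the az_up fold is
    # applied in AZ only, and the length/library factors cancel in the ratio
    # up to the two conditions' library-size draw (shared across genes)
    ratio <- log2(cm[azUp, "AZ_t24_WT"] / cm[azUp, "NAZ_t24_WT"])
    libShift <- stats::median(log2(cm[tr$class == "null", "AZ_t24_WT"] /
                                   cm[tr$class == "null", "NAZ_t24_WT"]))
    expect_true(all(abs((ratio - libShift) -
                        tr[azUp, "true_log2_fold"]) < 0.5))
    m <- mean(ratio - libShift)
    expect_gt(m, 3.7)
    expect_lt(m, 5.3)
})

test_that("all-null fractions with zero noise give exactly flat experiments", {
    # the noise-free limit is exact in signal mode (no counting noise)
    se <- simulateExperiment(
        designSpec(nGenes = 60, platform = "microarray", seed = 5),
        effectSpec(classFractions = c(az_up = 0, shared_up = 0,
                                      shared_down = 0, null = 1),
                   cvNoise = 0, nearGateFraction = 0))
    cm <- conditionMeans(se)
    expect_equal(log2(cm[, "AZ_t72_WT"] / cm[, "AZ_t0_WT"]),
                 setNames(rep(0, 60), rownames(cm)))
    expect_equal(log2(cm[, "AZ_t48_WT"] / cm[, "NAZ_t48_WT"]),
                 setNames(rep(0, 60), rownames(cm)))
})

test_that("readcount mode plants effects in the WT genotype only", {
    se <- simulateExperiment(
        designSpec(nGenes = 300, platform = "readcount", nReplicates = 4,
                   seed = 13),
        effectSpec(foldRangeLog2 = c(4, 5), dispersion = 0.005))
    expect_identical(valueKind(se), "counts")
    expect_setequal(unique(colData(se)$genotype), c("hae-hsl2", "WT"))
    cm <- conditionMeans(se)
    tr <- plantedTruth(se)
    upId <- rownames(tr)[tr$true_log2_fold > 0]
    wtCol <- grep("_WT$", colnames(cm), value = TRUE)
    mutCol <- setdiff(colnames(cm), wtCol)
    expect_gt(min(log2(cm[upId, wtCol] / cm[upId, mutCol])), 3)
})

test_that("microarray mode yields positive signal with multiplicative noise", {
    se <- simulateExperiment(
        designSpec(nGenes = 100, platform = "microarray",
                   timepointsH = c(0, 4, 8, 12, 16, 20), nReplicates = 2,
                   seed = 2))
    expect_identical(valueKind(se), "signal")
    expect_true(all(assay(se) > 0))
    expect_equal(ncol(se), 2 * 6 * 2)
})

test_that("truth tables round-trip through the tab-delimited writer", {
    se <- simulateExperiment(designSpec(nGenes = 1000, seed = 21))
    tr <- plantedTruth(se)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTruth(tr, path)
    expect_equal(length(readLines(path)), 1001)  # header + one row per gene
    back <- readTruth(path)
    expect_identical(rownames(back), rownames(tr))
    expect_identical(back$class, tr$class)
    expect_equal(back$true_log2_fold, tr$true_log2_fold)
    expect_identical(back$length_bp, tr$length_bp)

    empty <- tr[0, ]
    writeTruth(empty, path)
    expect_equal(length(readLines(path)), 1)
})
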