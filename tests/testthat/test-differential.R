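test_that("log2 ratios follow the definition and are antisymmetric", {
    m <- matrix(c(8, 1, 4, 4, 0.1, 102.4), 3, 2, byrow = TRUE,
                dimnames = list(c("x", "y", "z"), c("A", "B")))
    r <- log2Ratio(m, "A", "B")
    expect_equal(unname(r), c(3, 0, -10))
    expect_equal(log2Ratio(m, "B", "A"), -r)
    expect_error(log2Ratio(m, "A", "nope"), "unknown condition")
})

test_that("contrast reversal negates and is an involution", {
    expect_equal(reverseContrast(2.5), -2.5)
    expect_equal(reverseContrast(0), 0)
    m <- matrix(rnorm(12), 3)
    expect_equal(reverseContrast(reverseContrast(m)), m)
    df <- data.frame(gene = c("a", "b"), log2_fc = c(1.5, -2))
    rev <- reverseContrast(df)
    expect_equal(rev$log2_fc, c(-1.5, 2))
    expect_identical(rev$gene, df$gene)  # non-numeric columns untouched
})

test_that("the contrast test matches a textbook Welch t computed by hand", {
    a <- c(10, 10.1, 9.9); b <- c(1000, 1010, 990)
    p <- testContrast(a, b)
    expect_lt(p, 0.015)
    # independent implementation of Welch's statistic on log2 values
    la <- log2(a); lb <- log2(b)
    v1 <- var(la) / 3; v2 <- var(lb) / 3
    tstat <- (mean(la) - mean(lb)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
    expect_equal(p, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("degenerate contrasts are handled as documented", {
    expect_equal(testContrast(c(2, 3, 4), c(2, 3, 4)), 1)
    expect_equal(suppressWarnings(testContrast(5, c(1, 2, 3))), 1)
    expect_warning(testContrast(5, c(1, 2, 3)), "fewer than 2")
    expect_error(testContrast(numeric(), c(1, 2)), "empty")
    expect_error(testContrast(c(-1, 2, 3), c(1, 2, 3)), "positive")
    expect_equal(testContrast(c(4, 4, 4), c(4, 4, 4)), 1)
    p0 <- testContrast(c(4, 4, 4), c(8, 8, 8))
    expect_gt(p0, 0)
    expect_lt(p0, 1e-100)
})

test_that("Welch decisions agree with exact permutation on small samples", {
    set.seed(88)
    agree <- 0; n <- 120
    for (i in seq_len(n)) {
        shift <- sample(c(0, 0, 2^runif(1, 1, 4)), 1)
        a <- 2^(rnorm(4, 3, 0.5))
        b <- 2^(rnorm(4, 3, 0.5)) * max(shift, 1)
        welch <- testContrast(a, b) < 0.015
        perm <- permutationP(a, b) < 0.015
        agree <- agree + (welch == perm)
    }
    expect_gte(agree / n, 0.95)
})

test_that("classification flags match the hand examples", {
    fix <- randomDiffFixture(3, boundaryProb = 0)
    d <- fix$diff
    times <- c(12, 24, 48, 72)
    # gene 1: clean significant up-regulation at 48 h
    for (t in times) {
        d[1, sprintf("log2_t0_AZ_t%g", t)] <- ifelse(t == 48, 3.2, 0.5)
        d[1, sprintf("pvalue_t%g", t)] <- ifelse(t == 48, 0.01, 0.5)
        # gene 2: boundary fold, never changed under the strict rule
        d[2, sprintf("log2_t0_AZ_t%g", t)] <- 3.0
        d[2, sprintf("pvalue_t%g", t)] <- 0.001
        # gene 3: null
        d[3, sprintf("log2_t0_AZ_t%g", t)] <- 0
        d[3, sprintf("pvalue_t%g", t)] <- 1
        d[3, sprintf("log2_az_naz_t%g", t)] <- 0
    }
    d[3, "log2_az_naz_t0"] <- 0
    got <- classifyGenes(d)
    expect_identical(got$changed_up, c(TRUE, FALSE, FALSE))
    expect_identical(got$significant_changed, c(TRUE, FALSE, FALSE))
    expect_identical(got$changed_down, c(FALSE, FALSE, FALSE))
    expect_false(got$az_specific[3])
})

test_that("a significant p at a sub-threshold fold does not qualify", {
    fix <- randomDiffFixture(1, boundaryProb = 0)
    d <- fix$diff
    for (t in c(12, 24, 48, 72)) {
        d[1, sprintf("log2_t0_AZ_t%g", t)] <- ifelse(t == 24, 3.5, 2.0)
        d[1, sprintf("pvalue_t%g", t)] <- ifelse(t == 24, 0.5, 0.001)
    }
    got <- classifyGenes(d)
    expect_true(got$changed_up)          # 3.5 > 3 at 24 h
    expect_false(got$significant_changed)  # but p < 0.015 only where fold <= 3
})

test_that("classification agrees with the straight-loop oracle", {
    set.seed(202)
    for (i in 1:50) {
        fix <- randomDiffFixture(40)
        got <- suppressMessages(classifyGenes(fix$diff))
        want <- oracleClassify(fix$t0, fix$azm, fix$pm)
        expect_identical(got$changed_up, want$changed_up)
        expect_identical(got$changed_down, want$changed_down)
        expect_identical(got$az_specific, want$az_specific)
        expect_identical(got$significant_changed, want$significant_changed)
    }
})

test_that("flag sets shrink as thresholds tighten", {
    set.seed(33)
    fix <- randomDiffFixture(200)
    base <- suppressMessages(classifyGenes(fix$diff))
    tighter <- suppressMessages(
        classifyGenes(fix$diff, thresholdConfig(foldLog2 = 4)))
    expect_true(all(which(tighter$changed_up) %in% which(base$changed_up)))
    expect_true(all(which(tighter$changed_down) %in%
                    which(base$changed_down)))
    stricterP <- suppressMessages(
        classifyGenes(fix$diff, thresholdConfig(pvalueMax = 0.001)))
    expect_true(all(which(stricterP$significant_changed) %in%
                    which(base$significant_changed)))
    expect_error(thresholdConfig(pvalueMax = 1.5), "between 0 and 1")
    expect_error(thresholdConfig(foldLog2 = -1), "positive")
})

test_that("flag consistency invariants hold on simulated data", {
    se <- computeRPKM(simulateExperiment(designSpec(nGenes = 250, seed = 9)))
    gp <- gateProfile("soybean_rnaseq")
    fl <- applyFloor(se[applyGate(se, gp), ], gp@floor)
    d <- classifyGenes(differentialTable(fl))
    expect_false(any(d$changed_up & d$changed_down))
    expect_true(all(which(d$significant_changed) %in% which(d$changed_up)))
    ratioCols <- grep("^log2_", colnames(d))
    expect_true(all(is.finite(as.matrix(as.data.frame(d[, ratioCols])))))
    pCols <- grep("^pvalue_", colnames(d))
    pm <- as.matrix(as.data.frame(d[, pCols]))
    expect_true(all(pm > 0 & pm <= 1))
})

test_that("transcriptome share is the percent of the expressed total", {
    m <- matrix(c(50, 150, 800, 10, 40, 950), 3, 2,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    expect_equal(unname(transcriptomeShare(m, "a", "s1")), 5)
    expect_equal(unname(transcriptomeShare(m, c("a", "b", "c"), "s1")), 100)
    expect_equal(unname(transcriptomeShare(m, character(), "s1")), 0)
    expect_equal(unname(transcriptomeShare(m, c("a", "b"), "s2")), 5)
    expect_error(transcriptomeShare(m, "zz", "s1"), "absent")
    expect_error(transcriptomeShare(m, "a", "s9"), "unknown sample")
    m0 <- m; m0[, 2] <- 0
    expect_error(transcriptomeShare(m0, "a", "s2"), "zero total")
})

test_that("the genotype contrast orients log2 fold as WT over mutant", {
    se <- simulateExperiment(
        designSpec(nGenes = 200, platform = "readcount", nReplicates = 4,
                   seed = 31),
        effectSpec(foldRangeLog2 = c(4, 5)))
    fl <- applyFloor(se, 1.0)
    d <- genotypeDifferential(fl)
    tr <- plantedTruth(se)
    upId <- rownames(tr)[tr$true_log2_fold > 0]
    expect_gt(median(d[upId, "log2_fc"]), 3)
    expect_identical(S4Vectors::metadata(d)$numerator, "WT")
    # reversal gives the mutant/WT orientation
    expect_equal(reverseContrast(d$log2_fc), -d$log2_fc)
})
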