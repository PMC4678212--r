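test_that("RPKM matches hand arithmetic and the per-cell oracle", {
    # 10 reads on a 1000 bp gene in a 1,000,000-read library -> RPKM 10
    counts <- matrix(c(10, 999990), 2, 1,
                     dimnames = list(c("gA", "gB"), "AZ_t0_r1"))
    se <- toyExperiment(counts, "counts", lengths = c(1000L, 2000L))
    expect_equal(assay(computeRPKM(se))["gA", 1], 10.0)

    set.seed(404)
    for (rep in 1:5) {
        nr <- sample(3:20, 1); nc <- sample(2:6, 1)
        m <- matrix(rpois(nr * nc, 50), nr,
                    dimnames = list(sprintf("g%02d", 1:nr),
                                    sprintf("AZ_t0_r%d", 1:nc)))
        lens <- sample(500:5000, nr)
        se <- toyExperiment(m, "counts", lengths = lens)
        got <- assay(computeRPKM(se))
        want <- oracleRPKM(m, lens)
        expect_lt(max(abs(got - want) / pmax(want, 1e-300)), 1e-12)
    }
})

test_that("RPKM preserves zeros and is invariant to library scaling", {
    m <- matrix(c(0, 5, 20, 0, 7, 3), 3, 2,
                dimnames = list(c("a", "b", "c"),
                                c("AZ_t0_r1", "AZ_t0_r2")))
    se <- toyExperiment(m, "counts", lengths = c(800L, 1200L, 3000L))
    r1 <- assay(computeRPKM(se))
    expect_equal(r1["a", 1], 0)
    m2 <- m; m2[, 2] <- m2[, 2] * 2   # doubled library, same composition
    r2 <- assay(computeRPKM(toyExperiment(m2, "counts",
                                          lengths = c(800L, 1200L, 3000L))))
    expect_equal(r2[, 2], r1[, 2])
})

test_that("RPKM errors name the offending sample or gene", {
    m <- matrix(c(1, 1, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("AZ_t0_r1", "AZ_t0_r2")))
    se <- toyExperiment(m, "counts", lengths = c(1000L, 1000L))
    expect_error(computeRPKM(se), "AZ_t0_r2")
    se2 <- toyExperiment(m[, 1, drop = FALSE], "counts",
                         lengths = c(1000L, NA))
    expect_error(computeRPKM(se2), "\\bb\\b")
    expect_error(computeRPKM(toyExperiment(m, "rpkm")), "counts")
})

test_that("gate strictness follows the platform profiles at the boundary", {
    # three replicates per condition whose means straddle the thresholds
    buildSe <- function(geneMeans, kind) {
        nCond <- length(geneMeans[[1]])
        m <- do.call(rbind, lapply(geneMeans, function(mu) rep(mu, each = 3)))
        dimnames(m) <- list(sprintf("g%d", seq_along(geneMeans)),
                            as.vector(vapply(seq_len(nCond), function(t)
                                sprintf("AZ_t%d_r%d", t - 1, 1:3),
                                character(3))))
        toyExperiment(m, kind)
    }
    soy <- buildSe(list(c(0.4, 0.9, 1.0, 0.2), c(0.4, 0.99, 0.8, 0.2),
                        c(0, 0, 0, 0)), "rpkm")
    got <- applyGate(soy, gateProfile("soybean_rnaseq"))
    expect_identical(got, "g1")   # mean exactly 1.0 passes the >= gate

    tom <- buildSe(list(c(2, 10, 3), c(2, 10.01, 3), c(0, 0, 0)), "signal")
    expect_identical(applyGate(tom, gateProfile("tomato_microarray")), "g2")

    ara <- buildSe(list(c(10, 10), c(11, 2), c(0, 0)), "counts")
    expect_identical(applyGate(ara, gateProfile("arabidopsis_readcount")),
                     "g2")
})

test_that("gate refuses mismatched value kinds and shrinks with threshold", {
    se <- computeRPKM(simulateExperiment(designSpec(nGenes = 150, seed = 4)))
    expect_error(applyGate(se, gateProfile("tomato_microarray")), "signal")
    sets <- lapply(c(0.5, 1, 2, 5, 10), function(thr)
        applyGate(se, gateProfile("custom", threshold = thr, strict = TRUE,
                                  floor = 0.1, valueKind = "rpkm")))
    for (i in seq_len(length(sets) - 1))
        expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("the gate is decided on unfloored values", {
    # replicate signals (0, 0, 30): raw condition mean exactly 10 fails the
    # strict tomato gate; flooring first (1, 1, 30) would sneak it through
    m <- matrix(c(0, 0, 30, 20, 20, 20), 2, 3, byrow = TRUE,
                dimnames = list(c("edge", "ok"),
                                c("AZ_t0_r1", "AZ_t0_r2", "AZ_t0_r3")))
    se <- toyExperiment(m, "signal")
    expect_identical(applyGate(se, gateProfile("tomato_microarray")), "ok")
    floored <- applyFloor(se, 1.0)
    expect_identical(sort(applyGate(floored,
                                    gateProfile("tomato_microarray"))),
                     c("edge", "ok"))
})

test_that("flooring substitutes, is idempotent, monotone and validated", {
    expect_equal(applyFloor(matrix(0.05), 0.1)[1], 0.1)
    expect_equal(applyFloor(matrix(0.7), 1.0)[1], 1.0)
    m <- matrix(runif(30, 0, 2), 5)
    f1 <- applyFloor(m, 0.5)
    expect_identical(applyFloor(f1, 0.5), f1)
    expect_true(all(f1 >= 0.5))
    expect_true(all(f1[m >= 0.5] == m[m >= 0.5]))
    m2 <- m + 0.1   # x <= y implies floor(x) <= floor(y)
    expect_true(all(applyFloor(m2, 0.5) >= f1))
    expect_error(applyFloor(m, 0), "positive")
    expect_error(applyFloor(m, -1), "positive")
})

test_that("condition means average replicates within each condition", {
    m <- matrix(c(2, 4, 1, 1, 2, 6), 1,
                dimnames = list("g1", c("AZ_t0_r1", "AZ_t0_r2", "NAZ_t0_r1",
                                        "AZ_t12_r1", "AZ_t12_r2",
                                        "AZ_t12_r3")))
    cm <- conditionMeans(toyExperiment(m))
    expect_equal(cm["g1", "AZ_t0_WT"], 3)     # (2 + 4) / 2
    expect_equal(cm["g1", "NAZ_t0_WT"], 1)    # single replicate
    expect_equal(cm["g1", "AZ_t12_WT"], 3)    # (1 + 2 + 6) / 3
    conds <- attr(cm, "conditions")
    expect_equal(nrow(conds), 3)
    expect_identical(conds$tissue[conds$condition == "NAZ_t0_WT"], "NAZ")
})
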