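twoPopGd <- function(callsA, callsB, position = NULL) {
    calls <- cbind(callsA, callsB)
    if (is.null(position)) position <- seq_len(nrow(calls)) * 1000L
    makeGd(calls, position = position,
           populations = rep(c("A", "B"), c(ncol(callsA), ncol(callsB))))
}

test_that("heterozygosity: monomorphic markers contribute zero; hand fixture", {
    calls <- matrix(c(1L, 1L, 0L, 2L,
                      0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE)
    gd <- makeGd(calls)
    h <- heterozygosity(gd, byPopulation = FALSE)
    ## marker 1: Ho = 0.5, p = 0.5 -> He = 0.5; marker 2 monomorphic: 0, 0
    expect_equal(h$Ho, mean(c(0.5, 0)))
    expect_equal(h$He, mean(c(0.5, 0)))
})

test_that("heterozygosity approaches 0.5 under HWE at p = 0.5", {
    sim <- simulatePopulations(
        simConfig(nPopulations = 1, nPerPopulation = 200, nChromosomes = 2,
                  markersPerChromosome = 1000, fst = 0, missingRate = 0,
                  ancestralMafRange = c(0.4999, 0.5), seed = 71))
    h <- heterozygosity(sim$geno)
    expect_lt(abs(h$Ho - 0.5), 0.01)
    expect_lt(abs(h$He - 0.5), 0.01)
})

test_that("Wright per-marker values match hand computation", {
    ## equal sizes, p_A = 0.2, p_B = 0.8: (0.5 - 0.32) / 0.5 = 0.36
    ## exact frequencies from 5 samples: A has one het + ... 0.2 = 2/10
    cA <- matrix(c(2L, 0L, 0L, 0L, 0L), 1)       # p = 0.2
    cB <- matrix(c(0L, 2L, 2L, 2L, 2L), 1)       # p = 0.8
    ## identical frequencies and a fixed difference as extra markers
    cA <- rbind(cA, c(1L, 1L, 0L, 0L, 2L), rep(0L, 5))
    cB <- rbind(cB, c(1L, 1L, 0L, 0L, 2L), rep(2L, 5))
    fst <- pairwiseFst(twoPopGd(cA, cB), "A", "B", nBoot = 0)
    expect_equal(fst$perMarker$fst, c(0.36, 0, 1))
    ## monomorphic in both populations: undefined, never an outlier
    cA2 <- rbind(cA, rep(0L, 5)); cB2 <- rbind(cB, rep(0L, 5))
    fst2 <- pairwiseFst(twoPopGd(cA2, cB2), "A", "B", nBoot = 0)
    expect_true(is.na(fst2$perMarker$fst[4]))
    out <- fstOutlierScan(fst2, 0.5)
    expect_equal(out$marker_id, "m3")
    expect_equal(nrow(fstOutlierScan(fst2, 1)), 0L)    # strict >
    expect_equal(nrow(fstOutlierScan(fst2, 0)), 2L)    # all defined positive
})

test_that("Weir-Cockerham recovers the generating divergence; Wright shows
           its documented two-deme bias", {
    cfg <- simConfig(nPopulations = 2, nPerPopulation = 150,
                     nChromosomes = 5, markersPerChromosome = 1500,
                     fst = 0.05, missingRate = 0, seed = 81)
    sim <- simulatePopulations(cfg)
    wc <- pairwiseFst(sim$geno, "pop1", "pop2",
                      estimator = "weir_cockerham", nBoot = 200, seed = 5)
    expect_lt(abs(wc$fstOverall - 0.05), 0.01)
    ## seeded bootstrap is reproducible and brackets the estimate
    wc2 <- pairwiseFst(sim$geno, "pop1", "pop2",
                       estimator = "weir_cockerham", nBoot = 200, seed = 5)
    expect_identical(c(wc$ciLow, wc$ciHigh), c(wc2$ciLow, wc2$ciHigh))
    expect_true(wc$ciLow <= wc$fstOverall && wc$fstOverall <= wc$ciHigh)
    ## Wright/Nei pooled-frequency form: expectation F/(2-F) for two demes
    wr <- pairwiseFst(sim$geno, "pop1", "pop2", nBoot = 0)
    expect_lt(abs(wr$fstOverall - 0.05 / (2 - 0.05)), 0.01)
    ## per-marker Wright values stay in [0, 1]
    pm <- wr$perMarker$fst
    expect_true(all(pm[!is.na(pm)] >= 0 & pm[!is.na(pm)] <= 1))
    ## overall estimates are invariant to marker order
    shuf <- sim$geno[sample(seq_len(nMarkers(sim$geno))), ]
    expect_equal(pairwiseFst(shuf, "pop1", "pop2", nBoot = 0)$fstOverall,
                 wr$fstOverall)
})

test_that("pairwiseFstAll covers every population pair", {
    sim <- simulatePopulations(simConfig(nPerPopulation = 20,
                                         nChromosomes = 2, seed = 91))
    all3 <- pairwiseFstAll(sim$geno, nBoot = 0)
    expect_equal(nrow(all3), 3L)
    expect_setequal(paste(all3$pop_a, all3$pop_b),
                    c("CAS VBP", "CAS VRP", "VBP VRP"))
})

test_that("PCA separates diverged populations and respects its contracts", {
    sim <- simulatePopulations(
        simConfig(nPopulations = 2, nPerPopulation = 40, nChromosomes = 3,
                  markersPerChromosome = 600, fst = 0.1, missingRate = 0,
                  seed = 101))
    expect_warning(p <- pcaGenotypes(sim$geno), "zero-variance")
    expect_true(all(diff(p$eigenvalues) <= 1e-8))
    expect_true(all(p$eigenvalues >= 0))
    pc1 <- p$scores[, 1]
    pop <- populations(sim$geno)
    between <- (mean(pc1[pop == "pop1"]) - mean(pc1[pop == "pop2"]))^2
    within <- var(pc1[pop == "pop1"]) + var(pc1[pop == "pop2"])
    expect_gt(between, within)
    ## duplicated sample lands on coincident scores
    g <- genotypeCalls(sim$geno)
    g2 <- cbind(g, dup = g[, 1])
    si <- rbind(sampleInfo(sim$geno),
                data.frame(sample_id = "dup", population = "pop1"))
    gdDup <- GenotypeData(g2, markerInfo(sim$geno), si, sort = FALSE)
    pd <- suppressWarnings(pcaGenotypes(gdDup))
    d <- pd$scores[1, 1:2] - pd$scores[nrow(pd$scores), 1:2]
    expect_lt(sqrt(sum(d^2)), 1e-8)
})

test_that("IBD flags duplicates and scales for unrelated pairs", {
    sim <- simulatePopulations(
        simConfig(nPopulations = 1, nPerPopulation = 60, nChromosomes = 3,
                  markersPerChromosome = 800, fst = 0.01, missingRate = 0,
                  seed = 111))
    g <- genotypeCalls(sim$geno)
    g2 <- cbind(g, copy = g[, 1])
    si <- rbind(sampleInfo(sim$geno),
                data.frame(sample_id = "copy", population = "pop1"))
    gd <- GenotypeData(g2, markerInfo(sim$geno), si, sort = FALSE)
    ibd <- ibdEstimate(gd, pairs = rbind(c("pop1_1", "copy"),
                                         c("pop1_2", "pop1_3")))
    expect_gt(ibd$pi_hat[1], 0.95)
    expect_true(ibd$duplicate[1])
    expect_lt(ibd$pi_hat[2], 0.15)
    expect_false(ibd$first_degree[2])
})

test_that("GRM is symmetric with diagonal near 1 + inbreeding under HWE", {
    sim <- simulatePopulations(
        simConfig(nPopulations = 1, nPerPopulation = 80, nChromosomes = 3,
                  markersPerChromosome = 700, fst = 0, missingRate = 0,
                  seed = 121))
    G <- grmVanRaden(sim$geno)
    expect_equal(G, t(G))
    expect_lt(abs(mean(diag(G)) - 1), 0.05)
    bm <- grmBlockMeans(G, populations(sim$geno))
    expect_equal(nrow(bm), 1L)
    expect_lt(abs(bm$mean_relationship), 0.05)
})
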