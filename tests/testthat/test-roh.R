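## single-sample GenotypeData on one chromosome with given positions
rohGd <- function(g, pos) makeGd(matrix(g, ncol = 1), position = pos)

test_that("threshold boundaries: length, SNP count and gap rules", {
    ## 60 homozygotes spanning 999,000 bp: fails the 1 Mb rule
    pos <- as.integer(seq(1000, 1000 + 998999, length.out = 60))
    expect_equal(nrow(detectRoh(rohGd(rep(0L, 60), pos))), 0L)
    ## the same 60 homozygotes spanning exactly 1 Mb: accepted
    pos2 <- as.integer(seq(1000, 1000 + 999999, length.out = 60))
    seg <- detectRoh(rohGd(rep(0L, 60), pos2))
    expect_equal(nrow(seg), 1L)
    expect_equal(seg$length_bp, 1e6)
    expect_equal(seg$n_snps, 60L)
    ## 59 homozygotes spanning 1.2 Mb: fails the SNP-count rule
    pos3 <- as.integer(seq(1000, 1000 + 1.2e6, length.out = 59))
    expect_equal(nrow(detectRoh(rohGd(rep(0L, 59), pos3))), 0L)
    ## a heterozygote mid-run splits it into halves that each fail min_snps
    g <- rep(2L, 120); g[60] <- 1L
    pos4 <- as.integer(seq(1, 1.5e6, length.out = 120))
    expect_equal(nrow(detectRoh(rohGd(g, pos4))), 0L)
    expect_identical(bruteForceRoh(g, pos4), NULL)
    ## an over-gap (1,000,100 bp) breaks the run; exactly 1,000,000 does not
    gapPos <- c(seq(1, by = 2000, length.out = 60),
                seq(1, by = 2000, length.out = 60) + 118000 + 1000100)
    expect_equal(nrow(detectRoh(rohGd(rep(0L, 120), as.integer(gapPos)))), 0L)
    okPos <- c(seq(1, by = 2000, length.out = 60),
               seq(1, by = 2000, length.out = 60) + 118000 + 1000000)
    seg2 <- detectRoh(rohGd(rep(0L, 120), as.integer(okPos)))
    expect_equal(seg2$n_snps, 120L)
})

test_that("scanner set-equals the brute-force enumerator on random toys", {
    set.seed(2024)
    for (rep in 1:200) {
        inst <- randomRohInstance(sample(30:120, 1))
        params <- list(minLengthBp = sample(c(2e5, 5e5, 1e6), 1),
                       minSnps = sample(c(5, 10, 20), 1),
                       maxGapBp = sample(c(2e5, 5e5, 1e6), 1))
        got <- detectRoh(rohGd(inst$g, inst$pos),
                         minLengthBp = params$minLengthBp,
                         minSnps = params$minSnps,
                         maxGapBp = params$maxGapBp)
        want <- bruteForceRoh(inst$g, inst$pos, params$minLengthBp,
                              params$minSnps, params$maxGapBp)
        if (is.null(want)) {
            expect_equal(nrow(got), 0L)
        } else {
            expect_equal(got[, c("start_bp", "end_bp", "n_snps")],
                         want[, c("start_bp", "end_bp", "n_snps")],
                         ignore_attr = TRUE)
        }
    }
})

test_that("raising minima never adds runs; relaxing the gap never removes", {
    set.seed(77)
    for (rep in 1:30) {
        inst <- randomRohInstance(150)
        gd <- rohGd(inst$g, inst$pos)
        base <- nrow(detectRoh(gd, 3e5, 8, maxGapBp = 5e5))
        expect_lte(nrow(detectRoh(gd, 6e5, 8, maxGapBp = 5e5)), base)
        expect_lte(nrow(detectRoh(gd, 3e5, 16, maxGapBp = 5e5)), base)
        expect_gte(nrow(detectRoh(gd, 3e5, 8, maxGapBp = 1e6)), base)
    }
})

test_that("heterozygote noise only ever shrinks total ROH coverage", {
    sim <- simulatePopulations(simConfig(nPopulations = 1,
                                         nPerPopulation = 20,
                                         nChromosomes = 4, seed = 15,
                                         missingRate = 0))
    spec <- sampleSegmentSpec(sim$geno, 30, c(1.5e6, 6e6), seed = 16)
    pl <- plantAutozygousSegments(sim$geno, spec, seed = 17,
                                  truth = sim$truth)
    clean <- sum(detectRoh(pl$geno)$length_bp)
    noisy <- applyNoise(pl$geno, 0, 0.01, seed = 18)
    expect_lte(sum(detectRoh(noisy)$length_bp), clean)
})

test_that("unsorted marker maps are rejected, never silently re-sorted", {
    expect_error(
        GenotypeData(matrix(0L, 2, 1),
                     data.frame(marker_id = c("a", "b"), chromosome = "1",
                                position_bp = c(10L, 5L),
                                allele1 = "A", allele2 = "G"),
                     data.frame(sample_id = "s", population = "p"),
                     sort = FALSE),
        "sorted")
})

test_that("summaries match hand computation and count ROH-free individuals", {
    samples <- data.frame(sample_id = c("a", "b", "c"),
                          population = c("P1", "P1", "P2"))
    seg <- data.frame(
        sample_id = c("a", "a", "a", "b", "c"),
        population = c("P1", "P1", "P1", "P1", "P2"),
        chromosome = c("1", "1", "2", "3", "1"),
        start_bp = c(1e6, 5e6, 1e6, 1e6, 1e6),
        end_bp = c(3.5e6, 6.2e6, 10e6, 5e6, 17.5e6),
        n_snps = 100L, stringsAsFactors = FALSE)
    seg$length_bp <- seg$end_bp - seg$start_bp + 1
    seg$length_class <- rohLengthClass(seg$length_bp)
    s <- summarizeRoh(seg, samples)
    p1 <- s$perPopulation[s$perPopulation$population == "P1", ]
    expect_equal(p1$total_roh, 4L)
    expect_equal(p1$min_count, 1L)
    expect_equal(p1$max_count, 3L)
    expect_equal(p1$mean_count, 2)
    expect_equal(p1$mean_length_bp,
                 mean(seg$length_bp[seg$population == "P1"]))
    ## per-class counts: P1 has 2.5 Mb, 1.2 Mb, 9 Mb, 4 Mb runs
    pc <- s$perClass[s$perClass$population == "P1", ]
    expect_equal(pc$count[pc$length_class == "<2Mb"], 1L)
    expect_equal(pc$count[pc$length_class == "2-4Mb"], 1L)
    expect_equal(pc$count[pc$length_class == "4-8Mb"], 1L)
    expect_equal(pc$count[pc$length_class == "8-16Mb"], 1L)
    expect_equal(sum(pc$count), p1$total_roh)
    expect_equal(sum(pc$frequency), 1)
    ## individuals without ROH still appear with count 0
    none <- summarizeRoh(seg[0, ], samples)
    expect_equal(none$perIndividual$n_roh, c(0L, 0L, 0L))
})

test_that("length classes are left-closed right-open", {
    expect_equal(as.character(rohLengthClass(c(1.9e6, 2e6, 4e6, 8e6, 16e6,
                                               40e6))),
                 c("<2Mb", "2-4Mb", "4-8Mb", "8-16Mb", ">16Mb", ">16Mb"))
    ## a single 2.5 Mb run for one individual
    samples <- data.frame(sample_id = "a", population = "P")
    seg <- data.frame(sample_id = "a", population = "P", chromosome = "1",
                      start_bp = 1e6, end_bp = 3.5e6 - 1, n_snps = 80L,
                      length_bp = 2.5e6,
                      length_class = rohLengthClass(2.5e6))
    s <- summarizeRoh(seg, samples)
    expect_equal(s$perIndividual$n_roh, 1L)
    expect_equal(s$perIndividual$mean_length_bp, 2.5e6)
    expect_equal(as.character(seg$length_class), "2-4Mb")
})

test_that("chromosome coverage conserves totals and zeros empty chromosomes", {
    sim <- simulatePopulations(simConfig(nPopulations = 1,
                                         nPerPopulation = 10,
                                         nChromosomes = 5, seed = 19,
                                         missingRate = 0))
    spec <- sampleSegmentSpec(sim$geno, 12, c(1.5e6, 4e6), seed = 20)
    spec <- spec[spec$chromosome != "5", , drop = FALSE]
    pl <- plantAutozygousSegments(sim$geno, spec, seed = 21,
                                  truth = sim$truth)
    seg <- detectRoh(pl$geno)
    cov <- chromosomeCoverage(seg, pl$geno)
    expect_equal(sum(cov$n_roh), nrow(seg))
    expect_equal(sum(cov$frequency), 1)
    expect_equal(cov$n_roh[cov$chromosome == "5"], 0L)
    ## per-chromosome detected counts equal planted counts
    planted <- table(factor(spec$chromosome, levels = cov$chromosome))
    expect_equal(cov$n_roh, as.integer(planted))
})
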