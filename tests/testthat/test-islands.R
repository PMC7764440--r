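## 5 individuals, 30 markers at 1 kb spacing on one chromosome
islandFixture <- function() {
    makeGd(matrix(0L, 30, 5), position = seq_len(30) * 1000L,
           populations = "P")
}

segRow <- function(sid, start, end, chrom = "1") {
    data.frame(sample_id = sid, population = "P", chromosome = chrom,
               start_bp = start, end_bp = end, n_snps = 10L,
               length_bp = end - start + 1,
               length_class = rohLengthClass(end - start + 1),
               stringsAsFactors = FALSE)
}

test_that("occurrence counts individuals covering each marker, once each", {
    gd <- islandFixture()
    expect_true(all(occurrenceProfile(segRow("s1", 1, 1)[0, ], gd,
                                      "P")$occurrence == 0))
    seg <- segRow("s1", 10000, 20000)
    prof <- occurrenceProfile(seg, gd, "P")
    expect_equal(prof$occurrence, as.integer(seq_len(30) %in% 10:20))
    ## two segments of the same individual never double-count a marker
    seg2 <- rbind(segRow("s1", 10000, 20000), segRow("s1", 15000, 25000),
                  segRow("s2", 12000, 13000))
    prof2 <- occurrenceProfile(seg2, gd, "P")
    expect_equal(max(prof2$occurrence), 2L)
    expect_equal(prof2$occurrence[12:13], c(2L, 2L))
    expect_equal(prof2$occurrence[21:25], rep(1L, 5))
})

test_that("occurrence equals a brute-force membership count on random sets", {
    set.seed(303)
    gd <- islandFixture()
    mi <- markerInfo(gd)
    segs <- do.call(rbind, lapply(1:25, function(i) {
        st <- sample(28000, 1)
        segRow(paste0("s", sample(5, 1)), st, st + sample(5000, 1))
    }))
    prof <- occurrenceProfile(segs, gd, "P")
    brute <- vapply(mi$position_bp, function(p) {
        length(unique(segs$sample_id[segs$start_bp <= p &
                                     segs$end_bp >= p]))
    }, integer(1))
    expect_equal(prof$occurrence, brute)
})

test_that("top-SNP thresholding: rank arithmetic and tie semantics", {
    prof <- data.frame(marker_id = paste0("m", 1:200), chromosome = "1",
                       position_bp = 1:200 * 1000L,
                       occurrence = c(200:1))
    top <- topSnpThreshold(prof, 0.01)
    expect_equal(top$threshold, 199L)          # rank ceil(0.01*200) = 2
    expect_equal(nrow(top$topSnps), 2L)
    ## ties at the threshold are included, so the set may exceed 1%
    prof$occurrence <- c(rep(50L, 5), rep(10L, 195))
    top2 <- topSnpThreshold(prof, 0.01)
    expect_equal(top2$threshold, 50L)
    expect_equal(nrow(top2$topSnps), 5L)
    ## uniform profile: everything tied at the threshold, with a warning
    prof$occurrence <- rep(7L, 200)
    expect_warning(top3 <- topSnpThreshold(prof, 0.01), "uniform")
    expect_equal(nrow(top3$topSnps), 200L)
    ## top_fraction = 1 returns all markers with any occurrence
    expect_equal(nrow(topSnpThreshold(prof, 1)$topSnps), 200L)
    ## all-zero profile: empty set plus warning
    prof$occurrence <- 0L
    expect_warning(top4 <- topSnpThreshold(prof, 0.01), "all-zero")
    expect_equal(nrow(top4$topSnps), 0L)
})

test_that("island construction merges by gap and keeps TOP_SNP bounds", {
    top <- data.frame(marker_id = paste0("m", 1:5), chromosome = "1",
                      position_bp = c(1e6, 1.5e6, 2.2e6, 5e6, 7.1e6),
                      occurrence = c(5L, 8L, 6L, 9L, 4L))
    isl <- buildIslands(top, mergeGapBp = 1e6, population = "P")
    expect_equal(nrow(isl), 3L)
    expect_equal(isl$start_bp, c(1e6, 5e6, 7.1e6))
    expect_equal(isl$end_bp, c(2.2e6, 5e6, 7.1e6))
    expect_equal(isl$n_top_snps, c(3L, 1L, 1L))
    expect_equal(isl$max_occurrence, c(8L, 9L, 4L))
    ## a single TOP_SNP gives a degenerate start = end region
    expect_equal(isl$length_bp[2], 1)
    ## two SNPs exactly 2 Mb apart stay separate at the default gap
    two <- top[c(1, 3), ]; two$position_bp <- c(1e6, 3e6)
    expect_equal(nrow(buildIslands(two)), 2L)
    ## exactly at the merge gap they fuse
    two$position_bp <- c(1e6, 2e6)
    expect_equal(nrow(buildIslands(two)), 1L)
    ## every TOP_SNP lies inside exactly one island
    hits <- vapply(top$position_bp, function(p)
        sum(isl$start_bp <= p & isl$end_bp >= p), integer(1))
    expect_true(all(hits == 1L))
})

test_that("annotation intersection uses >= 1 bp overlap, inclusive output", {
    isl <- data.frame(chromosome = "1", start_bp = 1e6, end_bp = 2e6,
                      population = "P", stringsAsFactors = FALSE)
    feats <- data.frame(chromosome = "1",
                        start_bp = c(2e6 + 1, 1.5e6, 2e6, 999999),
                        end_bp = c(3e6, 1.6e6, 2.5e6, 999999),
                        name = c("abut", "inside", "edge", "leftout"),
                        class = "gene", stringsAsFactors = FALSE)
    ann <- intersectAnnotation(isl, feats)
    expect_setequal(ann$hits$name, c("inside", "edge"))
    expect_equal(ann$annotated$n_features, 2L)
    bad <- data.frame(chromosome = "1", start_bp = 10, end_bp = 5,
                      name = "x", class = "gene")
    expect_error(intersectAnnotation(isl, bad), "line 1")
})

test_that("annotation intersection matches brute force and is symmetric", {
    set.seed(404)
    isl <- data.frame(chromosome = sample(c("1", "2"), 40, TRUE),
                      start_bp = sample(1e6, 40), stringsAsFactors = FALSE)
    isl$end_bp <- isl$start_bp + sample(5e4, 40)
    isl$population <- "P"
    feats <- data.frame(chromosome = sample(c("1", "2"), 60, TRUE),
                        start_bp = sample(1e6, 60),
                        stringsAsFactors = FALSE)
    feats$end_bp <- feats$start_bp + sample(5e4, 60)
    feats$name <- paste0("g", 1:60)
    feats$class <- "gene"
    ann <- intersectAnnotation(isl, feats)
    brute <- 0L
    for (i in seq_len(nrow(isl))) for (j in seq_len(nrow(feats))) {
        if (isl$chromosome[i] == feats$chromosome[j] &&
            isl$start_bp[i] <= feats$end_bp[j] &&
            feats$start_bp[j] <= isl$end_bp[i]) brute <- brute + 1L
    }
    expect_equal(nrow(ann$hits), brute)
    ## swapping the roles of islands and features gives the same pair count
    featsAsIsl <- data.frame(chromosome = feats$chromosome,
                             start_bp = feats$start_bp,
                             end_bp = feats$end_bp, population = "P",
                             stringsAsFactors = FALSE)
    islAsFeat <- data.frame(chromosome = isl$chromosome,
                            start_bp = isl$start_bp, end_bp = isl$end_bp,
                            name = paste0("i", seq_len(nrow(isl))),
                            class = "island", stringsAsFactors = FALSE)
    expect_equal(nrow(intersectAnnotation(featsAsIsl, islAsFeat)$hits),
                 brute)
})

test_that("feature files round-trip through BED and GFF3 readers", {
    bed <- tempfile(fileext = ".bed")
    ## BED is 0-based half-open: [999, 2000) is 1000..2000 inclusive
    writeLines(c("1\t999\t2000\tGENE1", "2\t0\t100\tGENE2"), bed)
    f <- readFeatures(bed)
    expect_equal(f$start_bp, c(1000L, 1L))
    expect_equal(f$end_bp, c(2000L, 100L))
    expect_equal(f$name, c("GENE1", "GENE2"))
    gff <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 paste("1", "test", "gene", "1000", "2000", ".", "+", ".",
                       "ID=g1;Name=GENE1", sep = "\t")), gff)
    g <- readFeatures(gff)
    expect_equal(g$start_bp, 1000L)
    expect_equal(g$end_bp, 2000L)
    expect_equal(g$name, "GENE1")
    expect_equal(g$class, "gene")
})

test_that("cross-population sharing produces exact Venn partitions", {
    islA <- data.frame(chromosome = "1", start_bp = c(1e6, 5e6),
                       end_bp = c(2e6, 6e6), population = "A")
    islB <- data.frame(chromosome = "1", start_bp = 1.5e6, end_bp = 2.5e6,
                       population = "B")
    islC <- data.frame(chromosome = "1", start_bp = 1.8e6, end_bp = 3e6,
                       population = "C")
    genes <- list(A = c("g1", "g2", "g3"),
                  B = c("g2", "g3", "g4"),
                  C = c("g3", "g4", "g6"))
    sh <- crossPopulationSharing(list(A = islA, B = islB, C = islC), genes)
    expect_equal(sh$sharedRegions$start_bp, 1.8e6)
    expect_equal(sh$sharedRegions$end_bp, 2e6)
    vc <- sh$vennCounts
    getCount <- function(p) vc$count[vc$partition == p]
    expect_equal(getCount("A"), 1L)            # g1
    expect_equal(getCount("A+B"), 1L)          # g2
    expect_equal(getCount("A+B+C"), 1L)        # g3
    expect_equal(getCount("B+C"), 1L)          # g4
    expect_equal(getCount("C"), 1L)            # g6
    expect_equal(sum(vc$count), length(unique(unlist(genes))))
    ## identical sets: everything in the full intersection
    shSame <- crossPopulationSharing(list(A = islA, B = islA),
                                     list(A = c("x", "y"), B = c("x", "y")))
    expect_equal(shSame$vennCounts$count[
        shSame$vennCounts$partition == "A+B"], 2L)
    expect_equal(sum(shSame$sharedRegions$end_bp -
                     shSame$sharedRegions$start_bp + 1),
                 sum(islA$end_bp - islA$start_bp + 1))
    ## disjoint sets: empty intersection
    shDisj <- crossPopulationSharing(
        list(A = islA, B = transform(islA, start_bp = start_bp + 1e7,
                                     end_bp = end_bp + 1e7)))
    expect_equal(nrow(shDisj$sharedRegions), 0L)
})
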