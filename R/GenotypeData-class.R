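#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end reduce findOverlaps
#'   countOverlaps pintersect
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom GenomeInfoDb seqlevels seqnames
#' @importFrom stats rbinom rbeta runif cor lm coef setNames var quantile
#' @importFrom utils read.table write.table packageVersion
NULL

## Genotype codes: integer copies of allele2 (0 = hom allele1, 1 = het,
## 2 = hom allele2), NA = missing call.  Markers are rows, samples columns.

#' Cattle autosome labels
#'
#' The autosome set used by default throughout the package: chromosomes
#' "1".."29" of the ARS-UCD1.2 bovine assembly naming scheme.  Non-autosomal
#' markers (X, Y, MT, unplaced scaffolds) are accepted at load time and
#' flagged for removal by [qcFilter()].
#'
#' @return Character vector `"1"` .. `"29"`.
#' @export
#' @examples
#' cattleAutosomes()
cattleAutosomes <- function() as.character(1:29)

#' GenotypeData: SNP-array genotypes with marker map and sample metadata
#'
#' An S4 container (a [SummarizedExperiment::RangedSummarizedExperiment])
#' holding one assay `"calls"`: an integer matrix of markers x samples with
#' codes 0 (homozygous allele1), 1 (heterozygous), 2 (homozygous allele2) and
#' `NA` (missing).  Marker coordinates (1-based bp) live in `rowRanges()`
#' with metadata columns `marker_id`, `allele1`, `allele2`; sample metadata
#' (`sample_id`, `population`) in `colData()`.
#'
#' Validity requires unique marker and sample identifiers, genotype codes in
#' \{0, 1, 2, NA\}, and marker positions non-decreasing within each
#' chromosome (strictly increasing positions are enforced at construction by
#' sorting; duplicated positions are allowed, as on real chips).
#'
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- character(0)
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        g <- SummarizedExperiment::assay(object, "calls")
        if (!is.integer(g) && !is.numeric(g))
            msg <- c(msg, "calls must be numeric")
        bad <- g[!is.na(g)]
        if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
            msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    need <- c("marker_id", "allele1", "allele2")
    if (!all(need %in% colnames(S4Vectors::mcols(rr))))
        msg <- c(msg, "rowRanges must carry marker_id, allele1, allele2")
    else if (anyDuplicated(S4Vectors::mcols(rr)$marker_id))
        msg <- c(msg, "marker_ids must be unique")
    if (!all(c("sample_id", "population") %in%
             colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must carry sample_id and population")
    else if (anyDuplicated(SummarizedExperiment::colData(object)$sample_id))
        msg <- c(msg, "sample_ids must be unique")
    ## position order within chromosome
    chr <- as.character(GenomeInfoDb::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    if (length(pos) > 1L) {
        ok <- all(tapply(pos, chr, function(p) !is.unsorted(p)))
        if (!isTRUE(ok))
            msg <- c(msg, "marker positions must be sorted within chromosome")
    }
    if (length(msg)) msg else TRUE
})

## natural chromosome ordering: numeric labels first (by value), then others
.chromOrder <- function(chr) {
    u <- unique(chr)
    num <- suppressWarnings(as.numeric(u))
    u[order(is.na(num), num, u)]
}

#' Construct a GenotypeData object
#'
#' @param calls Integer matrix, markers x samples, codes in \{0,1,2,NA\}
#'   (counts of `allele2`).
#' @param map `data.frame` with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based), `allele1`, `allele2` (single characters, `"0"`
#'   for unknown), one row per marker in the row order of `calls`.
#' @param sampleInfo `data.frame` with columns `sample_id` and `population`,
#'   one row per column of `calls`.
#' @param sort Sort markers by (chromosome, position)?  Default `TRUE`;
#'   sample order is never changed.
#'
#' @return A [GenotypeData] object.
#' @export
#' @examples
#' gd <- GenotypeData(
#'   calls = matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'                  dimnames = list(NULL, c("s1", "s2"))),
#'   map = data.frame(marker_id = c("m1", "m2"), chromosome = "1",
#'                    position_bp = c(100L, 200L),
#'                    allele1 = "A", allele2 = "G"),
#'   sampleInfo = data.frame(sample_id = c("s1", "s2"),
#'                           population = c("CAS", "VRP")))
#' gd
GenotypeData <- function(calls, map, sampleInfo, sort = TRUE) {
    stopifnot(is.matrix(calls), nrow(calls) == nrow(map),
              ncol(calls) == nrow(sampleInfo))
    storage.mode(calls) <- "integer"
    map$chromosome <- as.character(map$chromosome)
    if (sort) {
        lev <- .chromOrder(map$chromosome)
        o <- order(match(map$chromosome, lev), map$position_bp)
        map <- map[o, , drop = FALSE]
        calls <- calls[o, , drop = FALSE]
    }
    rr <- GRanges(seqnames = map$chromosome,
                  ranges = IRanges(start = map$position_bp, width = 1L))
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
        marker_id = as.character(map$marker_id),
        allele1 = as.character(map$allele1),
        allele2 = as.character(map$allele2))
    names(rr) <- S4Vectors::mcols(rr)$marker_id
    cd <- S4Vectors::DataFrame(
        sample_id = as.character(sampleInfo$sample_id),
        population = as.character(sampleInfo$population))
    rownames(cd) <- cd$sample_id
    dimnames(calls) <- list(names(rr), cd$sample_id)
    se <- SummarizedExperiment(assays = list(calls = calls),
                               rowRanges = rr, colData = cd)
    new("GenotypeData", se)
}

#' Accessors for GenotypeData
#'
#' `genotypeCalls()` returns the markers x samples integer code matrix;
#' `markerMap()` the marker `GRanges`; `markerInfo()` the marker map as a
#' `data.frame` (`marker_id`, `chromosome`, `position_bp`, `allele1`,
#' `allele2`); `sampleInfo()` a `data.frame` of `sample_id` and `population`;
#' `populations()` the per-sample population labels; `nMarkers()` /
#' `nSamples()` the dimensions.
#'
#' @param x A [GenotypeData] object.
#' @return See description.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname genotype-accessors
#' @export
markerMap <- function(x) SummarizedExperiment::rowRanges(x)

#' @rdname genotype-accessors
#' @export
markerInfo <- function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(marker_id = S4Vectors::mcols(rr)$marker_id,
               chromosome = as.character(GenomeInfoDb::seqnames(rr)),
               position_bp = GenomicRanges::start(rr),
               allele1 = S4Vectors::mcols(rr)$allele1,
               allele2 = S4Vectors::mcols(rr)$allele2,
               row.names = NULL)
}

#' @rdname genotype-accessors
#' @export
sampleInfo <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(sample_id = cd$sample_id, population = cd$population,
               row.names = NULL)
}

#' @rdname genotype-accessors
#' @export
populations <- function(x) SummarizedExperiment::colData(x)$population

#' @rdname genotype-accessors
#' @export
nMarkers <- function(x) nrow(x)

#' @rdname genotype-accessors
#' @export
nSamples <- function(x) ncol(x)

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "markers x", ncol(object), "samples\n")
    pops <- table(populations(object))
    cat("populations:",
        paste(sprintf("%s (%d)", names(pops), as.integer(pops)),
              collapse = ", "), "\n")
    chr <- as.character(GenomeInfoDb::seqnames(markerMap(object)))
    cat("chromosomes:", length(unique(chr)), " missing rate:",
        sprintf("%.4f", mean(is.na(genotypeCalls(object)))), "\n")
})

#' Allele2 frequencies
#'
#' Frequency of `allele2` (the counted allele) per marker, from non-missing
#' calls, either pooled or within one group of samples.
#'
#' @param x A [GenotypeData] object.
#' @param samples Optional character vector of sample_ids (or logical/integer
#'   index) restricting the computation.
#' @return Numeric vector, one frequency per marker (`NaN` where no calls).
#' @export
alleleFreq <- function(x, samples = NULL) {
    g <- genotypeCalls(x)
    if (!is.null(samples)) g <- g[, samples, drop = FALSE]
    rowMeans(g, na.rm = TRUE) / 2
}

#' Marker call rates
#'
#' @param x A [GenotypeData] object.
#' @return `markerCallRate()`: non-missing fraction per marker;
#'   `sampleCallRate()`: non-missing fraction per sample.
#' @export
markerCallRate <- function(x) rowMeans(!is.na(genotypeCalls(x)))

#' @rdname markerCallRate
#' @export
sampleCallRate <- function(x) colMeans(!is.na(genotypeCalls(x)))

#' Autosomal length covered by markers
#'
#' Sum over chromosomes of (last marker position - first marker position + 1),
#' the denominator used for genomic inbreeding on simulated or chip data when
#' the assembly constant is not supplied.
#'
#' @param x A [GenotypeData] object or a marker `data.frame` from
#'   [markerInfo()].
#' @param autosomes Chromosome labels to include (default [cattleAutosomes()];
#'   `NULL` for all).
#' @return Total covered length in bp.
#' @export
coveredAutosomeLength <- function(x, autosomes = cattleAutosomes()) {
    mi <- if (is(x, "GenotypeData")) markerInfo(x) else x
    if (!is.null(autosomes)) mi <- mi[mi$chromosome %in% autosomes, ]
    if (!nrow(mi)) return(0)
    sum(tapply(mi$position_bp, mi$chromosome,
               function(p) max(p) - min(p) + 1))
}
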