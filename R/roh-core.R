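## Rule-based ROH detection.  A run extends over consecutive position-sorted
## markers while every call is a non-missing homozygote and the distance to
## the previous marker in the run is at most maxGapBp; any heterozygote,
## missing call, over-gap or chromosome end closes it.  Runs meeting both
## the SNP-count and bp-length minima are emitted.  Defaults are the
## 1000 kb / 60 SNP / zero-het / zero-missing / 1000 kb-gap rule set used
## for 150K-chip cattle data.

.lengthClassBreaks <- c(0, 2e6, 4e6, 8e6, 16e6, Inf)
.lengthClassLabels <- c("<2Mb", "2-4Mb", "4-8Mb", "8-16Mb", ">16Mb")

#' ROH length classes
#'
#' Left-closed right-open classes `[0,2)`, `[2,4)`, `[4,8)`, `[8,16)`,
#' `[16,Inf)` Mb, so a run of exactly 4,000,000 bp falls in `4-8Mb`.
#'
#' @param lengthBp Numeric vector of run lengths in bp.
#' @return Factor with levels `<2Mb`, `2-4Mb`, `4-8Mb`, `8-16Mb`, `>16Mb`.
#' @export
rohLengthClass <- function(lengthBp) {
    cut(lengthBp, breaks = .lengthClassBreaks, labels = .lengthClassLabels,
        right = FALSE)
}

.emptyRoh <- function() {
    data.frame(sample_id = character(), population = character(),
               chromosome = character(), start_bp = integer(),
               end_bp = integer(), n_snps = integer(), length_bp = numeric(),
               length_class = factor(character(),
                                     levels = .lengthClassLabels),
               stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity
#'
#' @param x A [GenotypeData] object with position-sorted markers (enforced;
#'   an unsorted map is an error, never silently re-sorted).
#' @param minLengthBp Minimum run length in bp (first to last SNP, 1-based
#'   inclusive: `end - start + 1`).
#' @param minSnps Minimum number of homozygous SNPs in the run.
#' @param maxHet,maxMissing Tolerated heterozygous / missing calls inside a
#'   run.  Only the strict rule (0, the default) is supported: any
#'   heterozygote or missing call closes the run.
#' @param maxGapBp Maximum distance between consecutive SNPs inside a run.
#' @return data.frame with columns `sample_id`, `population`, `chromosome`,
#'   `start_bp`, `end_bp` (positions of first/last SNP), `n_snps`,
#'   `length_bp`, `length_class`, sorted by (sample, chromosome, start).
#' @export
#' @examples
#' sim <- simulatePopulations(simConfig(nChromosomes = 2, seed = 3,
#'                                      markersPerChromosome = 100))
#' detectRoh(sim$geno)
detectRoh <- function(x, minLengthBp = 1e6, minSnps = 60,
                      maxHet = 0, maxMissing = 0, maxGapBp = 1e6) {
    stopifnot(minLengthBp >= 0, minSnps >= 0, maxGapBp >= 0)
    if (maxHet != 0 || maxMissing != 0)
        stop("only the strict rule maxHet = 0, maxMissing = 0 is supported")
    mi <- markerInfo(x)
    ord <- order(match(mi$chromosome, unique(mi$chromosome)), mi$position_bp)
    if (is.unsorted(ord))
        stop("marker map is not position-sorted within chromosome")
    g <- genotypeCalls(x)
    si <- sampleInfo(x)
    chromIdx <- split(seq_len(nrow(mi)), mi$chromosome)
    chromIdx <- chromIdx[unique(mi$chromosome)]      # keep map order
    out <- vector("list", 0L)
    for (s in seq_len(ncol(g))) {
        gi <- g[, s]
        for (cc in names(chromIdx)) {
            idx <- chromIdx[[cc]]
            elig <- !is.na(gi[idx]) & gi[idx] != 1L
            if (!any(elig)) next
            pos <- mi$position_bp[idx]
            r <- rle(elig)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in which(r$values)) {
                a <- starts[k]; b <- ends[k]
                pp <- pos[a:b]
                cut <- which(diff(pp) > maxGapBp)
                subStart <- c(1L, cut + 1L)
                subEnd <- c(cut, length(pp))
                for (u in seq_along(subStart)) {
                    i1 <- subStart[u]; i2 <- subEnd[u]
                    nsnp <- i2 - i1 + 1L
                    len <- pp[i2] - pp[i1] + 1
                    if (nsnp >= minSnps && len >= minLengthBp)
                        out[[length(out) + 1L]] <- data.frame(
                            sample_id = si$sample_id[s],
                            population = si$population[s],
                            chromosome = cc,
                            start_bp = pp[i1], end_bp = pp[i2],
                            n_snps = nsnp, length_bp = len,
                            stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (!length(out)) return(.emptyRoh())
    seg <- do.call(rbind, out)
    seg$length_class <- rohLengthClass(seg$length_bp)
    seg <- seg[order(match(seg$sample_id, si$sample_id),
                     match(seg$chromosome, unique(mi$chromosome)),
                     seg$start_bp), ]
    rownames(seg) <- NULL
    seg
}

#' Summarize runs of homozygosity
#'
#' Descriptive statistics at population, individual and length-class level.
#' Individuals with zero detected runs contribute a count of 0.
#'
#' @param segments data.frame from [detectRoh()].
#' @param samples data.frame with `sample_id` and `population` for every
#'   genotyped individual (from [sampleInfo()]), so that ROH-free
#'   individuals are counted.
#' @return A `RohSummary` list with data.frames `perPopulation` (total ROH,
#'   min/max/mean count per individual, min/max/mean segment length),
#'   `perIndividual` (count, total and mean length) and `perClass`
#'   (per population and class: count, within-population frequency, mean
#'   length).
#' @export
summarizeRoh <- function(segments, samples) {
    stopifnot(all(c("sample_id", "population") %in% names(samples)))
    cnt <- table(factor(segments$sample_id, levels = samples$sample_id))
    tot <- tapply(segments$length_bp,
                  factor(segments$sample_id, levels = samples$sample_id),
                  sum, default = 0)
    perInd <- data.frame(sample_id = samples$sample_id,
                         population = samples$population,
                         n_roh = as.integer(cnt),
                         total_length_bp = as.numeric(tot),
                         mean_length_bp = ifelse(cnt > 0,
                                                 as.numeric(tot) / as.integer(cnt),
                                                 NA_real_),
                         stringsAsFactors = FALSE)
    pops <- unique(samples$population)
    perPop <- do.call(rbind, lapply(pops, function(pp) {
        ind <- perInd[perInd$population == pp, ]
        sg <- segments[segments$population == pp, ]
        data.frame(population = pp,
                   total_roh = nrow(sg),
                   min_count = min(ind$n_roh), max_count = max(ind$n_roh),
                   mean_count = mean(ind$n_roh),
                   min_length_bp = if (nrow(sg)) min(sg$length_bp) else NA_real_,
                   max_length_bp = if (nrow(sg)) max(sg$length_bp) else NA_real_,
                   mean_length_bp = if (nrow(sg)) mean(sg$length_bp) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    cls <- factor(segments$length_class, levels = .lengthClassLabels)
    perClass <- do.call(rbind, lapply(pops, function(pp) {
        sel <- segments$population == pp
        tab <- table(cls[sel])
        data.frame(population = pp,
                   length_class = names(tab),
                   count = as.integer(tab),
                   frequency = if (sum(tab) > 0) as.integer(tab) / sum(tab)
                               else 0,
                   mean_length_bp = as.numeric(tapply(
                       segments$length_bp[sel], cls[sel], mean,
                       default = NA_real_)),
                   stringsAsFactors = FALSE)
    }))
    structure(list(perPopulation = perPop, perIndividual = perInd,
                   perClass = perClass), class = "RohSummary")
}

#' @export
print.RohSummary <- function(x, ...) {
    cat("ROH summary (", sum(x$perPopulation$total_roh), " runs, ",
        nrow(x$perIndividual), " individuals)\n", sep = "")
    print(x$perPopulation, row.names = FALSE)
    invisible(x)
}

#' Per-chromosome ROH coverage
#'
#' @param segments data.frame from [detectRoh()].
#' @param x A [GenotypeData] object (or [markerInfo()] data.frame) giving
#'   the chromosome universe; chromosomes without runs get zeros.
#' @return data.frame with `chromosome`, `n_roh`, `mean_length_bp`,
#'   `frequency` (fraction of all runs on the chromosome).
#' @export
chromosomeCoverage <- function(segments, x) {
    mi <- if (is(x, "GenotypeData")) markerInfo(x) else x
    chroms <- unique(mi$chromosome)
    f <- factor(segments$chromosome, levels = chroms)
    n <- table(f)
    tot <- max(1L, nrow(segments))
    data.frame(chromosome = chroms,
               n_roh = as.integer(n),
               mean_length_bp = as.numeric(tapply(segments$length_bp, f,
                                                  mean, default = NA_real_)),
               frequency = as.integer(n) / tot,
               stringsAsFactors = FALSE, row.names = NULL)
}
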