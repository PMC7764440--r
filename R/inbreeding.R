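## Genomic inbreeding: F_ROH = L_ROH / L_AUT (ratio of the summed ROH
## length of an individual to the autosomal length covered by markers) and
## the excess-homozygosity coefficient F = (O - E) / (L - E) in [-1, 1],
## 0 at Hardy-Weinberg equilibrium.

#' Autosomal genome length covered by the 150K bovine chip
#'
#' The ARS-UCD1.2 autosomal length covered by SNPs used as the default
#' F_ROH denominator for real cattle chip data.
#'
#' @return 2,487,082,459 (bp).
#' @export
bovineAutosomeLength <- function() 2487082459

#' Genomic inbreeding from ROH length
#'
#' `F_ROH = L_ROH / L_AUT`, the fraction of the SNP-covered autosomal
#' genome lying in runs of homozygosity.
#'
#' @param lRohBp Total ROH length of an individual in bp (vectorized).
#' @param lAutBp Autosomal length covered by markers, in bp; default the
#'   150K bovine chip constant [bovineAutosomeLength()].  For simulated
#'   data pass [coveredAutosomeLength()] of the dataset.
#' @return Numeric vector of F_ROH values.
#' @export
#' @examples
#' fRoh(557.46e6)   # 0.224 at the bovine chip denominator
fRoh <- function(lRohBp, lAutBp = bovineAutosomeLength()) {
    if (any(lAutBp <= 0)) stop("lAutBp must be positive")
    if (any(lRohBp < 0)) stop("lRohBp must be non-negative")
    lRohBp / lAutBp
}

#' Per-individual F_ROH records
#'
#' Computes, for every individual, the total ROH length and F_ROH overall,
#' per length class (five columns summing exactly to the total) and per
#' chromosome (all against the same denominator, so chromosome values sum
#' exactly to the total).
#'
#' @param segments data.frame from [detectRoh()].
#' @param samples data.frame of `sample_id`, `population` for all
#'   individuals (from [sampleInfo()]).
#' @param lAutBp F_ROH denominator in bp.
#' @param chromosomes Chromosome universe for the per-chromosome matrix;
#'   default the chromosomes present in `segments`.
#' @return list with `records` (data.frame: sample_id, population,
#'   l_roh_bp, f_roh, and `f_roh_<class>` columns) and `byChromosome`
#'   (samples x chromosomes matrix of F_ROH).
#' @export
frohRecords <- function(segments, samples, lAutBp = bovineAutosomeLength(),
                        chromosomes = NULL) {
    sid <- factor(segments$sample_id, levels = samples$sample_id)
    lsum <- tapply(segments$length_bp, sid, sum, default = 0)
    rec <- data.frame(sample_id = samples$sample_id,
                      population = samples$population,
                      l_roh_bp = as.numeric(lsum),
                      f_roh = fRoh(as.numeric(lsum), lAutBp),
                      stringsAsFactors = FALSE)
    for (cl in .lengthClassLabels) {
        sel <- segments$length_class == cl
        lc <- tapply(segments$length_bp[sel], sid[sel], sum, default = 0)
        rec[[paste0("f_roh_", gsub("[<>]", "", cl))]] <-
            fRoh(as.numeric(lc), lAutBp)
    }
    if (is.null(chromosomes)) chromosomes <- unique(segments$chromosome)
    byChrom <- sapply(chromosomes, function(cc) {
        sel <- segments$chromosome == cc
        as.numeric(tapply(segments$length_bp[sel], sid[sel], sum,
                          default = 0)) / lAutBp
    })
    byChrom <- matrix(byChrom, nrow = nrow(samples),
                      dimnames = list(samples$sample_id, chromosomes))
    list(records = rec, byChromosome = byChrom)
}

#' Excess-homozygosity inbreeding coefficient F
#'
#' For each individual, `F = (O - E) / (L - E)` where `O` is the observed
#' homozygote count over the individual's non-missing markers, `L` that
#' marker count, and `E = sum_j (1 - 2 p_j (1 - p_j))` the homozygote count
#' expected at Hardy-Weinberg equilibrium with allele frequencies `p_j`.
#' Missing calls are excluded from O, E and L.  F ranges from -1 (excess
#' heterozygosity) to +1 (complete homozygosity) and is 0 at equilibrium.
#' An individual with `L = E` (e.g. all its markers monomorphic) is
#' reported as `f = 0` with `degenerate = TRUE`.
#'
#' @param x A [GenotypeData] object.
#' @param freqBasis `"population"` (default) computes the expected counts
#'   from the individual's own population frequencies; `"pooled"` from the
#'   whole dataset.
#' @param freqs Optional vector of allele2 frequencies overriding
#'   `freqBasis` (one per marker).
#' @return data.frame with `sample_id`, `population`, `obs_hom`, `exp_hom`,
#'   `n_nonmissing`, `f`, `degenerate`.
#' @export
excessHomozygosityF <- function(x, freqBasis = c("population", "pooled"),
                                freqs = NULL) {
    freqBasis <- match.arg(freqBasis)
    g <- genotypeCalls(x)
    si <- sampleInfo(x)
    if (is.null(freqs)) {
        if (freqBasis == "pooled") {
            P <- matrix(alleleFreq(x), nrow = nrow(g), ncol = ncol(g))
        } else {
            P <- matrix(NA_real_, nrow = nrow(g), ncol = ncol(g))
            for (pp in unique(si$population)) {
                cols <- si$population == pp
                P[, cols] <- alleleFreq(x, si$sample_id[cols])
            }
        }
    } else {
        stopifnot(length(freqs) == nrow(g))
        P <- matrix(freqs, nrow = nrow(g), ncol = ncol(g))
    }
    nonmiss <- !is.na(g)
    obs <- colSums(nonmiss & g != 1L)
    eMat <- 1 - 2 * P * (1 - P)
    eMat[!nonmiss | !is.finite(eMat)] <- 0
    eMat[!nonmiss] <- 0
    expHom <- colSums(eMat * nonmiss)
    L <- colSums(nonmiss)
    denom <- L - expHom
    degen <- abs(denom) < 1e-12
    f <- ifelse(degen, 0, (obs - expHom) / denom)
    data.frame(sample_id = si$sample_id, population = si$population,
               obs_hom = as.numeric(obs), exp_hom = as.numeric(expHom),
               n_nonmissing = as.integer(L), f = as.numeric(f),
               degenerate = degen, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Population summary of F and F_ROH
#'
#' @param fTable data.frame from [excessHomozygosityF()].
#' @param frohTable `records` data.frame from [frohRecords()].
#' @return data.frame per population: mean observed/expected homozygotes,
#'   min/max/mean of F and of F_ROH.
#' @export
inbreedingSummary <- function(fTable, frohTable) {
    merged <- merge(fTable, frohTable[, c("sample_id", "f_roh")],
                    by = "sample_id")
    do.call(rbind, lapply(split(merged, merged$population), function(d)
        data.frame(population = d$population[1],
                   mean_obs_hom = mean(d$obs_hom),
                   mean_exp_hom = mean(d$exp_hom),
                   f_min = min(d$f), f_max = max(d$f), f_mean = mean(d$f),
                   f_roh_min = min(d$f_roh), f_roh_max = max(d$f_roh),
                   f_roh_mean = mean(d$f_roh),
                   stringsAsFactors = FALSE)))
}

#' Regression of F on F_ROH
#'
#' Ordinary least squares of the excess-homozygosity coefficient (y) on
#' F_ROH (x), per population.
#'
#' @param fTable data.frame from [excessHomozygosityF()].
#' @param frohTable `records` data.frame from [frohRecords()].
#' @return data.frame per population: `slope`, `intercept`, `r2`, `n`,
#'   `degenerate` (TRUE when F_ROH has zero variance; estimates NA).
#' @export
fVsFrohRegression <- function(fTable, frohTable) {
    merged <- merge(fTable, frohTable[, c("sample_id", "f_roh")],
                    by = "sample_id")
    do.call(rbind, lapply(split(merged, merged$population), function(d) {
        if (nrow(d) < 3)
            stop("need at least 3 individuals per population, got ",
                 nrow(d), " for ", d$population[1])
        if (var(d$f_roh) < 1e-20)
            return(data.frame(population = d$population[1],
                              slope = NA_real_, intercept = NA_real_,
                              r2 = NA_real_, n = nrow(d), degenerate = TRUE,
                              stringsAsFactors = FALSE))
        fit <- lm(f ~ f_roh, data = d)
        data.frame(population = d$population[1],
                   slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]),
                   r2 = summary(fit)$r.squared,
                   n = nrow(d), degenerate = FALSE,
                   stringsAsFactors = FALSE)
    }))
}
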