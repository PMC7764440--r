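## Fixture builders and independent oracles shared across test files.

## small GenotypeData from explicit pieces; calls is markers x samples
makeGd <- function(calls, chromosome = "1",
                   position = seq_len(nrow(calls)) * 1000L,
                   populations = "popA", ids = NULL, sort = TRUE) {
    m <- nrow(calls); n <- ncol(calls)
    if (is.null(ids)) ids <- paste0("s", seq_len(n))
    GenotypeData(
        calls,
        map = data.frame(marker_id = paste0("m", seq_len(m)),
                         chromosome = rep_len(chromosome, m),
                         position_bp = position,
                         allele1 = "A", allele2 = "G"),
        sampleInfo = data.frame(sample_id = ids,
                                population = rep_len(populations, n)),
        sort = sort)
}

## random single-sample instance for the ROH scanner oracle
randomRohInstance <- function(nMarkers, maxPos = 5e6) {
    pos <- sort(sample.int(maxPos, nMarkers))
    g <- sample(c(0L, 1L, 2L, NA), nMarkers, replace = TRUE,
                prob = c(0.45, 0.08, 0.42, 0.05))
    list(pos = pos, g = g)
}

## independent brute-force enumeration of maximal runs: a window [i, j] is
## valid iff every call is a non-missing homozygote and every internal gap
## is <= maxGapBp; maximal iff it cannot be extended either side; emit
## maximal windows meeting minSnps and minLengthBp
bruteForceRoh <- function(g, pos, minLengthBp = 1e6, minSnps = 60,
                          maxGapBp = 1e6) {
    n <- length(g)
    elig <- !is.na(g) & g != 1L
    out <- NULL
    for (i in seq_len(n)) {
        if (!elig[i]) next
        leftBlocked <- i == 1L || !elig[i - 1L] ||
            (pos[i] - pos[i - 1L]) > maxGapBp
        if (!leftBlocked) next
        j <- i
        while (j < n && elig[j + 1L] && (pos[j + 1L] - pos[j]) <= maxGapBp)
            j <- j + 1L
        nsnp <- j - i + 1L
        len <- pos[j] - pos[i] + 1
        if (nsnp >= minSnps && len >= minLengthBp)
            out <- rbind(out, data.frame(start_bp = pos[i], end_bp = pos[j],
                                         n_snps = nsnp, length_bp = len))
    }
    out
}

## Hudson-type two-population estimator (ratio of marker sums) from allele
## counts; an independent check on the package's estimators
hudsonFst <- function(gA, gB) {
    nA <- 2 * rowSums(!is.na(gA)); nB <- 2 * rowSums(!is.na(gB))
    pA <- rowSums(gA, na.rm = TRUE) / nA
    pB <- rowSums(gB, na.rm = TRUE) / nB
    ok <- nA >= 4 & nB >= 4
    num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
    den <- pA * (1 - pB) + pB * (1 - pA)
    sum(num[ok & den > 0]) / sum(den[ok & den > 0])
}

## genotype-level gamete transmission: one allele drawn from each parent
makeOffspring <- function(gPa, gPb) {
    draw <- function(g) ifelse(g == 0L, 0L,
                        ifelse(g == 2L, 1L, rbinom(length(g), 1L, 0.5)))
    out <- draw(gPa) + draw(gPb)
    out[is.na(gPa) | is.na(gPb)] <- NA_integer_
    as.integer(out)
}
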