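## Differentiation and relatedness: He/Ho, pairwise and per-marker Fixation
## Index (Wright/Nei pooled-frequency form and Weir-Cockerham variance
## components, both as ratio-of-sums over markers with a seeded marker
## bootstrap), PCA on standardized genotypes, PLINK-style method-of-moments
## IBD, and the VanRaden (method 1) genomic relationship matrix.

#' Observed and expected heterozygosity
#'
#' `Ho` is the mean over markers of the observed heterozygote fraction
#' (non-missing denominator); `He` the mean of `2p(1-p)` with `p` the
#' within-population allele frequency.  Monomorphic markers contribute 0 to
#' both.
#'
#' @param x A [GenotypeData] object.
#' @param byPopulation Compute per population (default) or pooled.
#' @return data.frame with `population`, `Ho`, `He`, `n_samples`.
#' @export
heterozygosity <- function(x, byPopulation = TRUE) {
    si <- sampleInfo(x)
    groups <- if (byPopulation) split(si$sample_id, si$population)
              else list(all = si$sample_id)
    do.call(rbind, lapply(names(groups), function(pp) {
        g <- genotypeCalls(x)[, groups[[pp]], drop = FALSE]
        het <- rowMeans(g == 1L, na.rm = TRUE)
        p <- rowMeans(g, na.rm = TRUE) / 2
        data.frame(population = pp,
                   Ho = mean(het, na.rm = TRUE),
                   He = mean(2 * p * (1 - p), na.rm = TRUE),
                   n_samples = length(groups[[pp]]),
                   stringsAsFactors = FALSE)
    }))
}

## per-marker genotyped counts, allele freqs and het fractions for a group
.popMarkerStats <- function(g) {
    n <- rowSums(!is.na(g))
    list(n = n, p = rowSums(g, na.rm = TRUE) / (2 * n),
         h = rowMeans(g == 1L, na.rm = TRUE))
}

#' Pairwise Fixation Index between two populations
#'
#' Per-marker and overall F_ST between two populations, with a seeded
#' bootstrap over markers for the 95% confidence interval.
#'
#' `estimator = "wright"` uses the Nei-style form on allele frequencies:
#' per marker, `(H_T - mean(H_S)) / H_T` with `H_T = 2 pbar (1 - pbar)` from
#' the unweighted mean of the two population frequencies; overall value is
#' the ratio of sums over markers.  This estimator carries a known downward
#' bias for two demes (expectation `F/(2-F)` under the Balding-Nichols
#' model) but matches the Fixation-Index convention of chip-analysis suites
#' and is the basis of the per-marker outlier scan.
#' `estimator = "weir_cockerham"` computes the Weir & Cockerham (1984)
#' variance components a, b, c per marker with overall
#' `sum(a) / sum(a+b+c)`; it is nearly unbiased for the divergence
#' parameter and is the choice for parameter-recovery checks.  Per-marker
#' Weir-Cockerham values can be slightly negative and are never clamped.
#'
#' Markers with fewer than 2 genotyped samples in either population are
#' skipped; markers monomorphic in the pooled pair have an undefined
#' per-marker value (`NA`, excluded from the outlier scan).
#'
#' @param x A [GenotypeData] object.
#' @param popA,popB Population labels.
#' @param estimator `"wright"` (default) or `"weir_cockerham"`.
#' @param nBoot Bootstrap replicates over markers (0 to skip the CI).
#' @param seed Integer seed for the bootstrap.
#' @return An `FstResult` list: `populations`, `estimator`, `fstOverall`,
#'   `ciLow`, `ciHigh`, `perMarker` (marker_id, chromosome, position_bp,
#'   fst), `nMarkersUsed`.
#' @export
pairwiseFst <- function(x, popA, popB,
                        estimator = c("wright", "weir_cockerham"),
                        nBoot = 1000, seed = 1) {
    estimator <- match.arg(estimator)
    si <- sampleInfo(x)
    stopifnot(popA %in% si$population, popB %in% si$population)
    g <- genotypeCalls(x)
    sA <- .popMarkerStats(g[, si$population == popA, drop = FALSE])
    sB <- .popMarkerStats(g[, si$population == popB, drop = FALSE])
    usable <- sA$n >= 2L & sB$n >= 2L
    if (estimator == "wright") {
        pbar <- (sA$p + sB$p) / 2
        ht <- 2 * pbar * (1 - pbar)
        hs <- (2 * sA$p * (1 - sA$p) + 2 * sB$p * (1 - sB$p)) / 2
        num <- ht - hs
        den <- ht
    } else {
        r <- 2
        nbar <- (sA$n + sB$n) / 2
        nc <- (sA$n + sB$n - (sA$n^2 + sB$n^2) / (sA$n + sB$n)) / (r - 1)
        pbar <- (sA$n * sA$p + sB$n * sB$p) / (r * nbar)
        s2 <- (sA$n * (sA$p - pbar)^2 + sB$n * (sB$p - pbar)^2) /
            ((r - 1) * nbar)
        hbar <- (sA$n * sA$h + sB$n * sB$h) / (r * nbar)
        a <- (nbar / nc) *
            (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                 (nbar - 1))
        b <- (nbar / (nbar - 1)) *
            (pbar * (1 - pbar) - s2 * (r - 1) / r -
                 hbar * (2 * nbar - 1) / (4 * nbar))
        cc <- hbar / 2
        num <- a
        den <- a + b + cc
    }
    num[!usable] <- NA; den[!usable] <- NA
    perMarkerFst <- ifelse(is.na(den) | den <= 0, NA_real_, num / den)
    used <- which(usable & !is.na(den) & den > 0)
    overall <- sum(num[used]) / sum(den[used])
    ciLow <- ciHigh <- NA_real_
    if (nBoot > 0 && length(used) > 1) {
        boots <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
            idx <- sample(used, length(used), replace = TRUE)
            sum(num[idx]) / sum(den[idx])
        }, numeric(1)))
        ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
        ciLow <- ci[1]; ciHigh <- ci[2]
    }
    mi <- markerInfo(x)
    structure(list(populations = c(popA, popB), estimator = estimator,
                   fstOverall = overall, ciLow = ciLow, ciHigh = ciHigh,
                   perMarker = data.frame(marker_id = mi$marker_id,
                                          chromosome = mi$chromosome,
                                          position_bp = mi$position_bp,
                                          fst = perMarkerFst,
                                          stringsAsFactors = FALSE),
                   nMarkersUsed = length(used), nBoot = nBoot),
              class = "FstResult")
}

#' @export
print.FstResult <- function(x, ...) {
    cat(sprintf("Fst %s vs %s (%s): %.4f [%.4f, %.4f], %d markers\n",
                x$populations[1], x$populations[2], x$estimator,
                x$fstOverall, x$ciLow, x$ciHigh, x$nMarkersUsed))
    invisible(x)
}

#' All pairwise population F_ST values
#'
#' @inheritParams pairwiseFst
#' @return data.frame with one row per population pair (`pop_a`, `pop_b`,
#'   `fst`, `ci_low`, `ci_high`, `n_markers`).
#' @export
pairwiseFstAll <- function(x, estimator = c("wright", "weir_cockerham"),
                           nBoot = 1000, seed = 1) {
    estimator <- match.arg(estimator)
    pops <- unique(populations(x))
    pairs <- utils::combn(pops, 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(pr) {
        r <- pairwiseFst(x, pr[1], pr[2], estimator, nBoot, seed)
        data.frame(pop_a = pr[1], pop_b = pr[2], fst = r$fstOverall,
                   ci_low = r$ciLow, ci_high = r$ciHigh,
                   n_markers = r$nMarkersUsed, stringsAsFactors = FALSE)
    }))
}

#' Per-marker F_ST outlier scan
#'
#' Markers whose per-marker Fixation Index strictly exceeds `threshold`
#' are flagged as differentiated (candidate selection signals); undefined
#' per-marker values are never outliers.
#'
#' @param fst An `FstResult` from [pairwiseFst()].
#' @param threshold Outlier threshold (default 0.5).
#' @return data.frame of outlier markers (subset of `fst$perMarker`).
#' @export
fstOutlierScan <- function(fst, threshold = 0.5) {
    stopifnot(inherits(fst, "FstResult"))
    pm <- fst$perMarker
    pm[!is.na(pm$fst) & pm$fst > threshold, , drop = FALSE]
}

#' Principal component analysis of genotypes
#'
#' Missing calls are mean-imputed; genotypes are centred by `2 p` and, with
#' `standardize = TRUE`, scaled by `sqrt(2 p (1 - p))` (pooled frequency
#' `p`).  Zero-variance (monomorphic) markers are dropped with a warning.
#' Scores are the eigendecomposition of the sample-by-sample covariance of
#' standardized genotypes, scaled so that `scores = vectors *
#' sqrt(eigenvalues)`.
#'
#' @param x A [GenotypeData] object; an LD-pruned marker set is
#'   recommended.
#' @param standardize Scale markers to unit drift variance.
#' @param nComponents Number of components to return.
#' @return A `PcaResult` list: `eigenvalues` (descending, >= 0), `scores`
#'   (samples x components, rownames = sample_id), `varianceExplained`.
#' @export
pcaGenotypes <- function(x, standardize = TRUE, nComponents = 10) {
    g <- t(genotypeCalls(x))                     # samples x markers
    p <- colMeans(g, na.rm = TRUE) / 2
    keep <- is.finite(p) & p > 0 & p < 1
    nzv <- apply(g, 2, function(v) stats::var(v, na.rm = TRUE))
    keep <- keep & is.finite(nzv) & nzv > 0
    if (any(!keep))
        warning(sum(!keep), " zero-variance marker(s) dropped from PCA")
    g <- g[, keep, drop = FALSE]; p <- p[keep]
    mu <- 2 * p
    X <- sweep(g, 2, mu)
    X[is.na(X)] <- 0                             # mean imputation
    if (standardize)
        X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
    K <- tcrossprod(X) / ncol(X)
    e <- eigen(K, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    k <- min(nComponents, length(vals))
    scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(vals[seq_len(k)]), k)
    rownames(scores) <- sampleInfo(x)$sample_id
    colnames(scores) <- paste0("PC", seq_len(k))
    structure(list(eigenvalues = vals,
                   scores = scores,
                   varianceExplained = vals / sum(vals)),
              class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
    cat("PCA:", nrow(x$scores), "samples;",
        "top eigenvalues:",
        paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)),
              collapse = ", "), "\n")
    invisible(x)
}

#' Method-of-moments identity-by-descent estimates
#'
#' PLINK-style moment estimators of the IBD state probabilities
#' (Z0, Z1, Z2) from identity-by-state counts and pooled allele
#' frequencies, without small-sample bias corrections; estimates are
#' clamped to `[0, 1]` and renormalised.  `PI_HAT = Z2 + Z1/2`.  Pairs
#' with `PI_HAT > 0.95` are flagged as potential duplicates, pairs with
#' `PI_HAT > 0.5` as first-degree relatives.
#'
#' @param x A [GenotypeData] object (pruned markers recommended).
#' @param pairs Optional 2-column matrix/data.frame of sample_id pairs;
#'   default all pairs.
#' @return data.frame with `id1`, `id2`, `z0`, `z1`, `z2`, `pi_hat`,
#'   `n_markers`, `duplicate`, `first_degree`.
#' @export
ibdEstimate <- function(x, pairs = NULL) {
    g <- genotypeCalls(x)                        # markers x samples
    si <- sampleInfo(x)
    p <- alleleFreq(x)
    keep <- is.finite(p) & p > 0 & p < 1
    g <- g[keep, , drop = FALSE]; p <- p[keep]
    q <- 1 - p
    e00 <- 2 * p^2 * q^2
    e01 <- 4 * p^3 * q + 4 * p * q^3
    e02 <- p^4 + q^4 + 4 * p^2 * q^2
    e11 <- 2 * p^2 * q + 2 * p * q^2
    e12 <- p^3 + q^3 + p^2 * q + p * q^2
    if (is.null(pairs)) {
        pairs <- t(utils::combn(si$sample_id, 2))
    }
    pairs <- as.matrix(pairs)
    out <- vector("list", nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
        i <- match(pairs[r, 1], si$sample_id)
        j <- match(pairs[r, 2], si$sample_id)
        if (is.na(i) || is.na(j)) stop("unknown sample in pairs")
        gi <- g[, i]; gj <- g[, j]
        ok <- !is.na(gi) & !is.na(gj)
        d <- abs(gi[ok] - gj[ok])
        N <- sum(ok)
        n0 <- sum(d == 2L); n1 <- sum(d == 1L); n2 <- sum(d == 0L)
        E00 <- sum(e00[ok]); E01 <- sum(e01[ok]); E02 <- sum(e02[ok])
        E11 <- sum(e11[ok]); E12 <- sum(e12[ok])
        z0 <- if (E00 > 0) n0 / E00 else 0
        z1 <- if (E11 > 0) (n1 - z0 * E01) / E11 else 0
        z2 <- if (N > 0) (n2 - z0 * E02 - z1 * E12) / N else 0
        z <- pmin(pmax(c(z0, z1, z2), 0), 1)
        if (sum(z) > 0) z <- z / sum(z)
        piHat <- min(max(z[3] + z[2] / 2, 0), 1)
        out[[r]] <- data.frame(id1 = pairs[r, 1], id2 = pairs[r, 2],
                               z0 = z[1], z1 = z[2], z2 = z[3],
                               pi_hat = piHat, n_markers = N,
                               duplicate = piHat > 0.95,
                               first_degree = piHat >= 0.5,
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Z Z' / (2 sum p (1 - p))` with `Z` the genotype matrix centred by
#' twice the pooled allele frequencies; missing calls contribute 0 to `Z`
#' (mean imputation).  Monomorphic markers are excluded.
#'
#' @param x A [GenotypeData] object.
#' @return Symmetric n x n matrix with sample_id dimnames.
#' @export
grmVanRaden <- function(x) {
    g <- t(genotypeCalls(x))
    p <- colMeans(g, na.rm = TRUE) / 2
    keep <- is.finite(p) & p > 0 & p < 1
    g <- g[, keep, drop = FALSE]; p <- p[keep]
    Z <- sweep(g, 2, 2 * p)
    Z[is.na(Z)] <- 0
    G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
    dimnames(G) <- list(sampleInfo(x)$sample_id, sampleInfo(x)$sample_id)
    G
}

#' Population-block means of a relationship matrix
#'
#' @param G Matrix from [grmVanRaden()].
#' @param populations Per-sample population labels in `G`'s order.
#' @return data.frame with `pop_a`, `pop_b`, `mean_relationship`
#'   (within-population blocks exclude the diagonal).
#' @export
grmBlockMeans <- function(G, populations) {
    pops <- unique(populations)
    out <- list()
    for (a in seq_along(pops)) for (b in a:length(pops)) {
        ia <- which(populations == pops[a])
        ib <- which(populations == pops[b])
        block <- G[ia, ib, drop = FALSE]
        if (a == b && length(ia) > 1) block <- block[upper.tri(block)]
        out[[length(out) + 1L]] <- data.frame(
            pop_a = pops[a], pop_b = pops[b],
            mean_relationship = mean(block), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Relatedness: IBD table plus genomic relationship matrix
#'
#' Convenience wrapper combining [ibdEstimate()], [grmVanRaden()] and
#' [grmBlockMeans()].
#'
#' @inheritParams ibdEstimate
#' @return list(ibd, grm, blockMeans).
#' @export
relatedness <- function(x, pairs = NULL) {
    G <- grmVanRaden(x)
    list(ibd = ibdEstimate(x, pairs), grm = G,
         blockMeans = grmBlockMeans(G, populations(x)))
}
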