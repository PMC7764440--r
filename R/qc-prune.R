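## Marker/sample QC and sliding-window LD pruning.  Call rate is the
## non-missing fraction; "call rate <= 0.90 deleted" is implemented as
## keep-if-strictly-greater.  Filter order is fixed: position/autosome ->
## sample call rate -> marker call rate, which makes the filter idempotent.

#' Quality-control filtering of markers and samples
#'
#' Removes markers without a positive chromosomal position or on
#' non-autosomal chromosomes, then samples with call rate at or below
#' `sampleCrMin`, then markers with call rate at or below `markerCrMin`
#' (rates computed on the retained samples).
#'
#' @param x A [GenotypeData] object.
#' @param sampleCrMin,markerCrMin Call-rate thresholds; a sample/marker is
#'   kept only if its non-missing fraction is strictly greater.
#' @param autosomes Chromosome labels treated as autosomal (default
#'   [cattleAutosomes()]).
#' @return list(geno = filtered [GenotypeData], report = `QcReport` list
#'   with `n_samples_in/out`, `n_markers_in/out`, `removed_samples`
#'   (sample_id, call_rate), `removed_markers` (marker_id, reason in
#'   \{no_position, non_autosomal, call_rate\})).
#' @export
qcFilter <- function(x, sampleCrMin = 0.90, markerCrMin = 0.90,
                     autosomes = cattleAutosomes()) {
    mi <- markerInfo(x)
    nIn <- nSamples(x); mIn <- nMarkers(x)
    noPos <- is.na(mi$position_bp) | mi$position_bp < 1L
    nonAuto <- !noPos & !(mi$chromosome %in% autosomes)
    removedMarkers <- data.frame(
        marker_id = mi$marker_id[noPos | nonAuto],
        reason = c(rep("no_position", sum(noPos)),
                   rep("non_autosomal", sum(nonAuto))),
        stringsAsFactors = FALSE)
    keepM <- !(noPos | nonAuto)
    x1 <- x[keepM, ]
    scr <- sampleCallRate(x1)
    keepS <- scr > sampleCrMin
    removedSamples <- data.frame(sample_id = sampleInfo(x1)$sample_id[!keepS],
                                 call_rate = unname(scr[!keepS]),
                                 stringsAsFactors = FALSE)
    if (!any(keepS)) stop("empty after QC: all samples removed")
    x2 <- x1[, keepS]
    mcr <- markerCallRate(x2)
    keepM2 <- mcr > markerCrMin
    if (any(!keepM2))
        removedMarkers <- rbind(removedMarkers, data.frame(
            marker_id = markerInfo(x2)$marker_id[!keepM2],
            reason = "call_rate", stringsAsFactors = FALSE))
    x3 <- x2[keepM2, ]
    if (nMarkers(x3) == 0L) stop("empty after QC: all markers removed")
    report <- list(n_samples_in = nIn, n_samples_out = nSamples(x3),
                   n_markers_in = mIn, n_markers_out = nMarkers(x3),
                   removed_samples = removedSamples,
                   removed_markers = removedMarkers)
    class(report) <- "QcReport"
    list(geno = x3, report = report)
}

#' @export
print.QcReport <- function(x, ...) {
    cat("QC: samples", x$n_samples_in, "->", x$n_samples_out,
        "; markers", x$n_markers_in, "->", x$n_markers_out, "\n")
    if (nrow(x$removed_markers))
        print(table(x$removed_markers$reason))
    invisible(x)
}

#' Sliding-window LD pruning
#'
#' Greedy pruning so that no retained marker pair within any
#' `windowSnps`-marker window on a chromosome has squared Pearson
#' correlation of genotype codes (pairwise-complete samples) above `r2Max`.
#' Windows advance by `stepSnps`; within a window, for each offending pair
#' the member with the lower minor-allele frequency is removed (ties: the
#' higher marker index).
#'
#' @param x A [GenotypeData] object (QC'd input recommended).
#' @param windowSnps Window size in markers (>= 2).
#' @param stepSnps Window step in markers.
#' @param r2Max Maximum tolerated r-squared.
#' @return Character vector of retained `marker_id`s, in map order.
#' @export
ldPrune <- function(x, windowSnps = 50, stepSnps = 5, r2Max = 0.5) {
    if (windowSnps < 2) stop("windowSnps must be >= 2")
    if (stepSnps < 1) stop("stepSnps must be >= 1")
    mi <- markerInfo(x)
    g <- genotypeCalls(x)
    p <- rowMeans(g, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep <- rep(TRUE, nrow(mi))
    for (cc in unique(mi$chromosome)) {
        idx <- which(mi$chromosome == cc)
        n <- length(idx)
        starts <- seq(1L, max(1L, n - 1L), by = stepSnps)
        for (s in starts) {
            w <- idx[s:min(s + windowSnps - 1L, n)]
            w <- w[keep[w]]
            if (length(w) < 2L) next
            r2 <- suppressWarnings(
                cor(t(g[w, , drop = FALSE]),
                    use = "pairwise.complete.obs"))^2
            r2[!is.finite(r2)] <- 0
            repeat {
                r2[lower.tri(r2, diag = TRUE)] <- 0
                off <- which(r2 > r2Max, arr.ind = TRUE)
                if (!nrow(off)) break
                ## handle the first offending pair, then re-scan
                i <- w[off[1, 1]]; j <- w[off[1, 2]]
                drop <- if (maf[i] < maf[j]) i
                        else if (maf[j] < maf[i]) j
                        else max(i, j)
                keep[drop] <- FALSE
                dd <- match(drop, w)
                r2[dd, ] <- 0; r2[, dd] <- 0
            }
        }
    }
    mi$marker_id[keep]
}
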