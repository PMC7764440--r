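## ROH islands: within-population per-marker occurrence counts, top-1%
## thresholding with tie inclusion, merge-by-gap interval construction,
## interval intersection with gene/QTL annotation (1-bp overlap; half-open
## arithmetic internally, 1-based inclusive coordinates in all outputs),
## and cross-population sharing with Venn partitions.

.segGRanges <- function(segments) {
    GRanges(seqnames = segments$chromosome,
            ranges = IRanges(start = segments$start_bp,
                             end = segments$end_bp))
}

#' Per-marker ROH occurrence profile
#'
#' For one population, counts per marker the number of individuals whose
#' detected runs cover the marker position (each individual at most once
#' per marker).
#'
#' @param segments data.frame from [detectRoh()].
#' @param x A [GenotypeData] object (marker universe).
#' @param population Population label; defaults to all segments supplied.
#' @return data.frame: `marker_id`, `chromosome`, `position_bp`,
#'   `occurrence`, plus attributes `population` and `n_individuals`.
#' @export
occurrenceProfile <- function(segments, x, population = NULL) {
    mi <- markerInfo(x)
    si <- sampleInfo(x)
    if (!is.null(population)) {
        segments <- segments[segments$population == population, ,
                             drop = FALSE]
        nInd <- sum(si$population == population)
    } else nInd <- nrow(si)
    cnt <- integer(nrow(mi))
    if (nrow(segments)) {
        mgr <- GRanges(mi$chromosome, IRanges(mi$position_bp, width = 1L))
        sgr <- .segGRanges(segments)
        hits <- GenomicRanges::findOverlaps(mgr, sgr)
        ## one count per (marker, individual)
        key <- unique(cbind(S4Vectors::queryHits(hits),
                            match(segments$sample_id,
                                  unique(segments$sample_id))[
                                      S4Vectors::subjectHits(hits)]))
        tab <- table(factor(key[, 1], levels = seq_len(nrow(mi))))
        cnt <- as.integer(tab)
    }
    out <- data.frame(marker_id = mi$marker_id, chromosome = mi$chromosome,
                      position_bp = mi$position_bp, occurrence = cnt,
                      stringsAsFactors = FALSE)
    attr(out, "population") <- population
    attr(out, "n_individuals") <- nInd
    out
}

#' Top-occurrence SNP threshold
#'
#' Ranks markers by ROH occurrence (descending); the threshold is the
#' occurrence at rank `ceiling(topFraction * M)`, and every marker with
#' occurrence at or above it is a TOP_SNP — ties are included, so the set
#' may exceed the nominal fraction.  An all-zero profile yields an empty
#' set with a warning.
#'
#' @param profile data.frame from [occurrenceProfile()].
#' @param topFraction Fraction of markers to select (default 0.01).
#' @return list(`threshold` = occurrence value, `topSnps` = subset of
#'   `profile` rows, position-sorted).
#' @export
topSnpThreshold <- function(profile, topFraction = 0.01) {
    stopifnot(topFraction > 0, topFraction <= 1)
    M <- nrow(profile)
    occ <- sort(profile$occurrence, decreasing = TRUE)
    thr <- occ[min(M, max(1L, ceiling(topFraction * M)))]
    if (thr == 0 && all(profile$occurrence == 0)) {
        warning("all-zero occurrence profile: no TOP_SNPs")
        return(list(threshold = 0L,
                    topSnps = profile[0, , drop = FALSE]))
    }
    sel <- profile$occurrence >= thr & profile$occurrence > 0
    if (all(sel[profile$occurrence > 0]) && length(unique(
        profile$occurrence[profile$occurrence > 0])) == 1L)
        warning("uniform occurrence profile: all markers tied at threshold")
    list(threshold = thr, topSnps = profile[sel, , drop = FALSE])
}

#' Build ROH islands from TOP_SNPs
#'
#' Consecutive TOP_SNPs on a chromosome are merged into one interval while
#' the inter-SNP distance is at most `mergeGapBp`; interval bounds are the
#' first/last TOP_SNP positions (a single TOP_SNP gives a degenerate
#' start = end region).
#'
#' @param topSnps data.frame of TOP_SNPs (from [topSnpThreshold()]).
#' @param mergeGapBp Maximum inter-SNP distance merged into one island.
#' @param population Optional label stored in the output.
#' @return data.frame: `chromosome`, `start_bp`, `end_bp`, `length_bp`,
#'   `n_top_snps`, `max_occurrence`, `population`.
#' @export
buildIslands <- function(topSnps, mergeGapBp = 1e6, population = NA) {
    if (!nrow(topSnps))
        return(data.frame(chromosome = character(), start_bp = integer(),
                          end_bp = integer(), length_bp = numeric(),
                          n_top_snps = integer(), max_occurrence = integer(),
                          population = character(),
                          stringsAsFactors = FALSE))
    gr <- GRanges(topSnps$chromosome,
                  IRanges(topSnps$position_bp, width = 1L))
    red <- GenomicRanges::reduce(gr, min.gapwidth = mergeGapBp)
    hits <- GenomicRanges::findOverlaps(gr, red)
    occ <- tapply(topSnps$occurrence[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), max)
    nsnp <- tabulate(S4Vectors::subjectHits(hits), nbins = length(red))
    out <- data.frame(chromosome = as.character(GenomeInfoDb::seqnames(red)),
                      start_bp = GenomicRanges::start(red),
                      end_bp = GenomicRanges::end(red),
                      stringsAsFactors = FALSE)
    out$length_bp <- out$end_bp - out$start_bp + 1
    out$n_top_snps <- nsnp
    out$max_occurrence <- as.integer(occ)
    out$population <- population
    out[order(match(out$chromosome, unique(topSnps$chromosome)),
              out$start_bp), , drop = FALSE]
}

#' Read gene/QTL annotation intervals
#'
#' Reads BED (0-based half-open, converted to 1-based inclusive) or GFF3
#' features via `rtracklayer`.  Feature names are taken from the BED name
#' column or the GFF3 `Name`/`gene_name`/`ID` attribute; the `class` column
#' holds the BED score column name ("feature") or the GFF3 type.
#'
#' @param path File path (`.bed`, `.gff`/`.gff3`).
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame: `chromosome`, `start_bp`, `end_bp`, `name`, `class`.
#' @export
readFeatures <- function(path, format = c("auto", "bed", "gff3")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
            "bed" else "gff3"
    gr <- rtracklayer::import(path, format = format)
    nm <- S4Vectors::mcols(gr)
    name <- if ("Name" %in% colnames(nm) && !all(is.na(nm$Name)))
        as.character(nm$Name)
    else if ("gene_name" %in% colnames(nm)) as.character(nm$gene_name)
    else if ("name" %in% colnames(nm)) as.character(nm$name)
    else if ("ID" %in% colnames(nm)) as.character(nm$ID)
    else paste0("feature_", seq_along(gr))
    cls <- if ("type" %in% colnames(nm)) as.character(nm$type)
           else "feature"
    data.frame(chromosome = as.character(GenomeInfoDb::seqnames(gr)),
               start_bp = GenomicRanges::start(gr),
               end_bp = GenomicRanges::end(gr),
               name = name, class = cls, stringsAsFactors = FALSE)
}

#' Intersect islands with annotation features
#'
#' Reports every (island, feature) pair overlapping by at least 1 bp.
#' Coordinates are 1-based inclusive on input and output; malformed
#' features (`end < start`) are rejected with their row number.
#'
#' @param islands data.frame from [buildIslands()].
#' @param features data.frame from [readFeatures()] (columns `chromosome`,
#'   `start_bp`, `end_bp`, `name`, optional `class`).
#' @return list(`annotated` = islands with added `genes` (comma-joined
#'   overlapping names) and `n_features`; `hits` = long data.frame of
#'   island/feature pairs; `classCounts` = features per class and
#'   population).
#' @export
intersectAnnotation <- function(islands, features) {
    bad <- which(features$end_bp < features$start_bp)
    if (length(bad))
        stop("malformed feature interval (end < start) at line ", bad[1])
    if (is.null(features$class)) features$class <- "feature"
    ann <- islands
    ann$genes <- ""
    ann$n_features <- 0L
    hits <- data.frame(chromosome = character(), start_bp = integer(),
                       end_bp = integer(), population = character(),
                       name = character(), class = character(),
                       stringsAsFactors = FALSE)
    if (nrow(islands) && nrow(features)) {
        igr <- GRanges(islands$chromosome,
                       IRanges(islands$start_bp, islands$end_bp))
        fgr <- GRanges(features$chromosome,
                       IRanges(features$start_bp, features$end_bp))
        ov <- GenomicRanges::findOverlaps(igr, fgr, minoverlap = 1L)
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        if (length(qh)) {
            hits <- data.frame(
                chromosome = islands$chromosome[qh],
                start_bp = islands$start_bp[qh],
                end_bp = islands$end_bp[qh],
                population = if ("population" %in% names(islands))
                    islands$population[qh] else NA,
                name = features$name[sh],
                class = features$class[sh],
                stringsAsFactors = FALSE)
            agg <- tapply(features$name[sh], qh,
                          function(v) paste(unique(v), collapse = ","))
            ann$genes[as.integer(names(agg))] <- unname(agg)
            cntTab <- table(qh)
            ann$n_features[as.integer(names(cntTab))] <-
                as.integer(cntTab)
        }
    }
    classCounts <- if (nrow(hits))
        as.data.frame(table(population = hits$population,
                            class = hits$class),
                      responseName = "count", stringsAsFactors = FALSE)
    else data.frame(population = character(), class = character(),
                    count = integer(), stringsAsFactors = FALSE)
    list(annotated = ann, hits = hits, classCounts = classCounts)
}

#' Cross-population sharing of islands and genes
#'
#' Region sharing is computed by interval intersection across all supplied
#' populations; gene sharing by name-set algebra, yielding the full Venn
#' partition (genes present in exactly each subset of populations).
#'
#' @param islandsByPop Named list of island data.frames (one per
#'   population).
#' @param genesByPop Named list of character vectors of gene names.
#' @return list(`sharedRegions` = intervals common to all populations;
#'   `vennCounts` = data.frame of partition (`+`-joined population subset),
#'   gene count and comma-joined genes).
#' @export
crossPopulationSharing <- function(islandsByPop, genesByPop = NULL) {
    stopifnot(length(islandsByPop) >= 2)
    grs <- lapply(islandsByPop, function(d)
        GenomicRanges::reduce(GRanges(d$chromosome,
                                      IRanges(d$start_bp, d$end_bp))))
    common <- Reduce(GenomicRanges::intersect, grs)
    sharedRegions <- data.frame(
        chromosome = as.character(GenomeInfoDb::seqnames(common)),
        start_bp = GenomicRanges::start(common),
        end_bp = GenomicRanges::end(common), stringsAsFactors = FALSE)
    vennCounts <- NULL
    if (!is.null(genesByPop)) {
        pops <- names(genesByPop)
        genesByPop <- lapply(genesByPop, unique)
        allGenes <- unique(unlist(genesByPop))
        member <- vapply(genesByPop, function(s) allGenes %in% s,
                         logical(length(allGenes)))
        member <- matrix(member, ncol = length(pops),
                         dimnames = list(allGenes, pops))
        key <- apply(member, 1, function(r)
            paste(pops[r], collapse = "+"))
        subsets <- unlist(lapply(seq_along(pops), function(k)
            utils::combn(pops, k, paste, collapse = "+")))
        tab <- table(factor(key, levels = subsets))
        genes <- tapply(allGenes, factor(key, levels = subsets),
                        function(v) paste(sort(v), collapse = ","),
                        default = "")
        vennCounts <- data.frame(partition = subsets,
                                 count = as.integer(tab),
                                 genes = as.character(genes),
                                 stringsAsFactors = FALSE, row.names = NULL)
    }
    list(sharedRegions = sharedRegions, vennCounts = vennCounts)
}

#' Export islands as BED
#'
#' Writes islands in BED format (0-based half-open), name =
#' `population`.
#'
#' @param islands data.frame from [buildIslands()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeIslandsBed <- function(islands, path) {
    bed <- data.frame(islands$chromosome,
                      islands$start_bp - 1L,       # 0-based half-open
                      islands$end_bp,
                      ifelse(is.na(islands$population), "island",
                             islands$population))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Export ROH segments as BED
#'
#' 0-based half-open intervals, name = sample_id.
#'
#' @param segments data.frame from [detectRoh()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeRohBed <- function(segments, path) {
    bed <- data.frame(segments$chromosome, segments$start_bp - 1L,
                      segments$end_bp, segments$sample_id)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
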