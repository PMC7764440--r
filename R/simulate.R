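## Balding-Nichols multi-population genotype simulator with planted
## autozygous tracts and full ground truth.  All randomness flows from one
## integer seed through .splitSeed(), one stream per operation, so stages
## are independently reproducible.

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

.splitSeed <- function(seed, stream) {
    as.integer((as.numeric(seed) * 7919 + 1103 * stream) %% 2147483629)
}

## minimum-norm least-squares per-population divergence from pairwise
## targets: fst_ij ~ (F_i + F_j) / 2 (Hudson expectation under the model)
.perPopulationF <- function(fstMatrix) {
    k <- nrow(fstMatrix)
    if (k == 1L) return(0)
    pairs <- which(upper.tri(fstMatrix), arr.ind = TRUE)
    A <- matrix(0, nrow(pairs), k)
    for (r in seq_len(nrow(pairs))) A[r, pairs[r, ]] <- 0.5
    b <- fstMatrix[pairs]
    sv <- svd(A)
    pos <- sv$d > 1e-12
    f <- sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos])
    pmin(pmax(as.vector(f), 0), 0.999)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulatePopulations()].  The
#' defaults emulate three moderately diverged alpine cattle breeds sampled on
#' a dense SNP chip, at desk scale: 3 populations x 50 individuals,
#' 29 chromosomes x 700 markers (~20K markers) at ~19 kb average spacing,
#' pairwise divergence matching the published breed comparisons
#' (0.019 to 0.052) and a 0.5% missing-call rate.
#'
#' @param nPopulations Number of populations.
#' @param nPerPopulation Individuals per population (recycled to
#'   `nPopulations`).
#' @param nChromosomes,markersPerChromosome,chromosomeLengthBp Genome
#'   geometry; marker positions are uniform random then sorted.
#' @param fst Pairwise divergence targets: a symmetric `nPopulations` matrix
#'   in `[0,1)`, or a scalar applied to every pair.
#' @param ancestralMafRange Ancestral minor-allele-frequency range (lo, hi]
#'   in (0, 0.5].
#' @param missingRate,hetErrorRate Noise rates in `[0,1)` passed to
#'   [applyNoise()].
#' @param populationNames Labels; default `CAS`, `VBP`, `VRP` for 3
#'   populations, else `pop1..`.
#' @param seed Mandatory integer seed.
#' @return A `SimConfig` list.
#' @export
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg$fst
simConfig <- function(nPopulations = 3,
                      nPerPopulation = 50,
                      nChromosomes = 29,
                      markersPerChromosome = 700,
                      chromosomeLengthBp = 13300000,
                      fst = NULL,
                      ancestralMafRange = c(0.05, 0.5),
                      missingRate = 0.005,
                      hetErrorRate = 0,
                      populationNames = NULL,
                      seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (is.null(populationNames))
        populationNames <- if (nPopulations == 3) c("CAS", "VBP", "VRP")
                           else paste0("pop", seq_len(nPopulations))
    if (is.null(fst)) {
        fst <- matrix(0.03, nPopulations, nPopulations)
        diag(fst) <- 0
        if (nPopulations == 3) {
            ## CAS-VBP 0.019, CAS-VRP 0.052, VBP-VRP 0.050
            fst[1, 2] <- fst[2, 1] <- 0.019
            fst[1, 3] <- fst[3, 1] <- 0.052
            fst[2, 3] <- fst[3, 2] <- 0.050
        }
    }
    if (length(fst) == 1L) {
        fst <- matrix(fst, nPopulations, nPopulations)
        diag(fst) <- 0
    }
    stopifnot(nrow(fst) == nPopulations, all(fst >= 0), all(fst < 1),
              isSymmetric(unname(fst)))
    stopifnot(length(ancestralMafRange) == 2,
              ancestralMafRange[1] > 0, ancestralMafRange[2] <= 0.5,
              ancestralMafRange[1] <= ancestralMafRange[2],
              missingRate >= 0, missingRate < 1,
              hetErrorRate >= 0, hetErrorRate < 1,
              nChromosomes >= 1, markersPerChromosome >= 1,
              chromosomeLengthBp >= markersPerChromosome)
    nPerPopulation <- rep_len(nPerPopulation, nPopulations)
    dimnames(fst) <- list(populationNames, populationNames)
    structure(list(nPopulations = nPopulations,
                   nPerPopulation = nPerPopulation,
                   nChromosomes = nChromosomes,
                   markersPerChromosome = markersPerChromosome,
                   chromosomeLengthBp = chromosomeLengthBp,
                   fst = fst,
                   ancestralMafRange = ancestralMafRange,
                   missingRate = missingRate,
                   hetErrorRate = hetErrorRate,
                   populationNames = populationNames,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
    cat("SimConfig:", x$nPopulations, "populations x",
        paste(x$nPerPopulation, collapse = "/"), "individuals;",
        x$nChromosomes, "chr x", x$markersPerChromosome, "markers\n")
    cat("per-population divergence:",
        paste(sprintf("%.3f", .perPopulationF(x$fst)), collapse = ", "),
        " seed:", x$seed, "\n")
    invisible(x)
}

.emptySegments <- function() {
    data.frame(sample_id = character(), chromosome = character(),
               start_bp = integer(), end_bp = integer(),
               first_marker = integer(), last_marker = integer(),
               n_markers = integer(), stringsAsFactors = FALSE)
}

#' Simulate structured populations (Balding-Nichols model)
#'
#' Each population k draws its allele frequency at marker j from
#' `Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)` around the ancestral frequency
#' `p`; genotypes are `Binomial(2, p_jk)`.  The per-population `F_k` are the
#' minimum-norm least-squares solution of the pairwise targets
#' `fst_ij = (F_i + F_j)/2`.  `F_k = 0` degenerates to `p_jk = p_j` exactly.
#' Missingness and heterozygote error are then applied per
#' `missingRate`/`hetErrorRate`.  Fixed seed gives bit-identical output.
#'
#' @param config A [simConfig()] object.
#' @return A list with elements `geno` ([GenotypeData]) and `truth`
#'   (`SimTruth`: `plantedSegments` data.frame, `subpopFreqs` markers x
#'   populations matrix of realized frequencies, `ancestralFreqs`,
#'   `perPopulationF`, `perIndividualFTarget`).
#' @export
#' @examples
#' sim <- simulatePopulations(simConfig(nChromosomes = 2, seed = 7,
#'                                      markersPerChromosome = 50))
#' sim$geno
simulatePopulations <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    cfg <- config
    m <- cfg$nChromosomes * cfg$markersPerChromosome
    k <- cfg$nPopulations
    Fk <- .perPopulationF(cfg$fst)
    out <- .withSeed(.splitSeed(cfg$seed, 1L), {
        pos <- unlist(lapply(seq_len(cfg$nChromosomes), function(cc)
            sort(sample.int(cfg$chromosomeLengthBp,
                            cfg$markersPerChromosome))))
        maf <- runif(m, cfg$ancestralMafRange[1], cfg$ancestralMafRange[2])
        flip <- runif(m) < 0.5          # counted allele not always minor
        p <- ifelse(flip, 1 - maf, maf)
        pk <- matrix(0, m, k, dimnames = list(NULL, cfg$populationNames))
        for (i in seq_len(k)) {
            if (Fk[i] <= 0) pk[, i] <- p
            else pk[, i] <- rbeta(m, p * (1 - Fk[i]) / Fk[i],
                                  (1 - p) * (1 - Fk[i]) / Fk[i])
        }
        calls <- matrix(NA_integer_, m, sum(cfg$nPerPopulation))
        col0 <- 0L
        for (i in seq_len(k)) {
            ni <- cfg$nPerPopulation[i]
            calls[, col0 + seq_len(ni)] <-
                rbinom(m * ni, 2L, rep(pk[, i], ni))
            col0 <- col0 + ni
        }
        list(pos = pos, p = p, pk = pk, calls = calls)
    })
    chrom <- rep(as.character(seq_len(cfg$nChromosomes)),
                 each = cfg$markersPerChromosome)
    map <- data.frame(marker_id = sprintf("snp_%s_%d", chrom, out$pos),
                      chromosome = chrom, position_bp = out$pos,
                      allele1 = "A", allele2 = "B",
                      stringsAsFactors = FALSE)
    ## chip ids must be unique even if two chromosomes share a position draw
    map$marker_id <- make.unique(map$marker_id, sep = "_")
    pops <- rep(cfg$populationNames, cfg$nPerPopulation)
    si <- data.frame(
        sample_id = paste0(pops, "_",
                           unlist(lapply(cfg$nPerPopulation, seq_len))),
        population = pops, stringsAsFactors = FALSE)
    gd <- GenotypeData(out$calls, map, si)
    if (cfg$missingRate > 0 || cfg$hetErrorRate > 0)
        gd <- applyNoise(gd, cfg$missingRate, cfg$hetErrorRate,
                         seed = .splitSeed(cfg$seed, 2L))
    ## truth frequencies follow the sorted marker order of gd
    mid <- match(S4Vectors::mcols(markerMap(gd))$marker_id, map$marker_id)
    truth <- structure(list(
        plantedSegments = .emptySegments(),
        subpopFreqs = out$pk[mid, , drop = FALSE],
        ancestralFreqs = out$p[mid],
        perPopulationF = setNames(Fk, cfg$populationNames),
        perIndividualFTarget = setNames(numeric(nrow(si)), si$sample_id)),
        class = "SimTruth")
    list(geno = gd, truth = truth)
}

#' @export
print.SimTruth <- function(x, ...) {
    cat("SimTruth:", nrow(x$plantedSegments), "planted segments;",
        nrow(x$subpopFreqs), "markers x", ncol(x$subpopFreqs),
        "population frequency draws\n")
    invisible(x)
}

#' Draw a random specification of non-overlapping autozygous segments
#'
#' Utility for validation studies: draws `nSegments` tuples
#' (sample, chromosome, start_bp, length_bp) uniformly, accepting only
#' segments that cover at least `minSnps` markers and do not overlap a
#' previously drawn segment of the same individual.
#'
#' @param x A [GenotypeData] object.
#' @param nSegments Number of segments to draw.
#' @param lengthRangeBp Length range (uniform draw).
#' @param minSnps Minimum markers a segment must span.
#' @param seed Integer seed.
#' @param maxTries Rejection-sampling cap.
#' @return data.frame with columns `sample_id`, `chromosome`, `start_bp`,
#'   `length_bp`.
#' @export
sampleSegmentSpec <- function(x, nSegments, lengthRangeBp = c(1.5e6, 2e7),
                              minSnps = 60, seed, maxTries = 100 * nSegments) {
    si <- sampleInfo(x)
    mi <- markerInfo(x)
    chroms <- unique(mi$chromosome)
    chromMax <- vapply(chroms,
                       function(cc) max(mi$position_bp[mi$chromosome == cc]),
                       numeric(1))
    .withSeed(seed, {
        picked <- vector("list", nSegments)
        got <- 0L; tries <- 0L
        while (got < nSegments && tries < maxTries) {
            tries <- tries + 1L
            cc <- sample(chroms, 1L)
            len <- round(runif(1, lengthRangeBp[1], lengthRangeBp[2]))
            if (len >= chromMax[[cc]]) next
            st <- sample.int(chromMax[[cc]] - len, 1L)
            en <- st + len - 1L
            pos <- mi$position_bp[mi$chromosome == cc]
            if (sum(pos >= st & pos <= en) < minSnps) next
            sid <- si$sample_id[sample.int(nrow(si), 1L)]
            ok <- TRUE
            if (got > 0L) {
                prev <- do.call(rbind, picked[seq_len(got)])
                same <- prev$sample_id == sid & prev$chromosome == cc
                if (any(same & prev$start_bp <= en &
                        prev$start_bp + prev$length_bp - 1L >= st))
                    ok <- FALSE
            }
            if (!ok) next
            got <- got + 1L
            picked[[got]] <- data.frame(sample_id = sid, chromosome = cc,
                                        start_bp = st, length_bp = len,
                                        stringsAsFactors = FALSE)
        }
        if (got < nSegments)
            stop("could not place ", nSegments, " segments in ", maxTries,
                 " tries")
        do.call(rbind, picked)
    })
}

#' Plant autozygous segments into a genotype matrix
#'
#' Within each requested segment every covered marker is set to a
#' non-missing homozygote by drawing a single allele from its population
#' frequency and duplicating it (so planted tracts keep realistic allele
#' content rather than a fixed allele).  With `flankHet = TRUE` (default)
#' the single marker immediately before and after each tract is set
#' heterozygous so that the planted boundary is identifiable by a detector:
#' a validation feature of the generator, not a property of real data.
#'
#' Segments that cover no marker are recorded with `n_markers = 0` and leave
#' the genotypes untouched.  Overlapping segments for one individual are an
#' error.
#'
#' @param x A [GenotypeData] object.
#' @param segments data.frame with columns `sample_id`, `chromosome`,
#'   `start_bp`, `length_bp` (see [sampleSegmentSpec()]).
#' @param seed Integer seed for the allele draws.
#' @param truth Optional `SimTruth` from [simulatePopulations()]; its
#'   realized per-population frequencies drive the allele draws and the
#'   planted segments are appended to it.  Without it, observed
#'   per-population frequencies are used.
#' @param flankHet Set the flanking markers heterozygous (see above).
#' @return list(geno = [GenotypeData], truth = `SimTruth`) where
#'   `truth$plantedSegments` records, per planted tract, the covered marker
#'   index range and bp bounds of the first/last covered marker.
#' @export
plantAutozygousSegments <- function(x, segments, seed, truth = NULL,
                                    flankHet = TRUE) {
    stopifnot(all(c("sample_id", "chromosome", "start_bp", "length_bp")
                  %in% names(segments)))
    mi <- markerInfo(x)
    si <- sampleInfo(x)
    g <- genotypeCalls(x)
    segments$chromosome <- as.character(segments$chromosome)
    segments$end_bp <- segments$start_bp + segments$length_bp - 1L
    ## bounds + overlap validation
    for (cc in unique(segments$chromosome)) {
        if (!cc %in% mi$chromosome)
            stop("segment on unknown chromosome ", cc)
    }
    if (any(segments$start_bp < 1L))
        stop("segment start before chromosome origin")
    bySample <- split(segments, segments$sample_id)
    for (sid in names(bySample)) {
        s <- bySample[[sid]]
        s <- s[order(s$chromosome, s$start_bp), ]
        byc <- split(s, s$chromosome)
        for (b in byc) {
            if (nrow(b) > 1L &&
                any(b$start_bp[-1] <= b$end_bp[-nrow(b)]))
                stop("overlapping segments for individual ", sid)
        }
    }
    if (is.null(truth)) {
        pops <- unique(si$population)
        pk <- vapply(pops, function(pp)
            alleleFreq(x, si$sample_id[si$population == pp]), numeric(nrow(mi)))
        pk <- matrix(pk, ncol = length(pops), dimnames = list(NULL, pops))
        truth <- structure(list(plantedSegments = .emptySegments(),
                                subpopFreqs = pk,
                                ancestralFreqs = alleleFreq(x),
                                perPopulationF = setNames(rep(NA_real_,
                                    length(pops)), pops),
                                perIndividualFTarget =
                                    setNames(numeric(nrow(si)),
                                             si$sample_id)),
                           class = "SimTruth")
    }
    rec <- vector("list", nrow(segments))
    .withSeed(seed, {
        for (r in seq_len(nrow(segments))) {
            sg <- segments[r, ]
            col <- match(sg$sample_id, si$sample_id)
            if (is.na(col)) stop("unknown sample ", sg$sample_id)
            idx <- which(mi$chromosome == sg$chromosome &
                         mi$position_bp >= sg$start_bp &
                         mi$position_bp <= sg$end_bp)
            if (!length(idx)) {
                rec[[r]] <- data.frame(sample_id = sg$sample_id,
                                       chromosome = sg$chromosome,
                                       start_bp = NA_integer_,
                                       end_bp = NA_integer_,
                                       first_marker = NA_integer_,
                                       last_marker = NA_integer_,
                                       n_markers = 0L,
                                       stringsAsFactors = FALSE)
                next
            }
            pcol <- match(si$population[col], colnames(truth$subpopFreqs))
            pj <- if (!is.na(pcol)) truth$subpopFreqs[idx, pcol]
                  else alleleFreq(x)[idx]
            pj[!is.finite(pj)] <- 0.5
            g[idx, col] <- ifelse(runif(length(idx)) < pj, 2L, 0L)
            if (flankHet) {
                onChrom <- which(mi$chromosome == sg$chromosome)
                before <- max(onChrom[onChrom < min(idx)], -Inf)
                after <- min(onChrom[onChrom > max(idx)], Inf)
                if (is.finite(before)) g[before, col] <- 1L
                if (is.finite(after)) g[after, col] <- 1L
            }
            rec[[r]] <- data.frame(sample_id = sg$sample_id,
                                   chromosome = sg$chromosome,
                                   start_bp = mi$position_bp[min(idx)],
                                   end_bp = mi$position_bp[max(idx)],
                                   first_marker = min(idx),
                                   last_marker = max(idx),
                                   n_markers = length(idx),
                                   stringsAsFactors = FALSE)
        }
    })
    planted <- do.call(rbind, rec)
    truth$plantedSegments <- rbind(truth$plantedSegments, planted)
    covered <- planted[planted$n_markers > 0L, ]
    if (nrow(covered)) {
        lsum <- tapply(as.numeric(covered$end_bp - covered$start_bp + 1),
                       covered$sample_id, sum)
        lAut <- coveredAutosomeLength(mi, autosomes = NULL)
        truth$perIndividualFTarget[names(lsum)] <-
            truth$perIndividualFTarget[names(lsum)] + lsum / lAut
    }
    out <- GenotypeData(g, mi, si, sort = FALSE)
    list(geno = out, truth = truth)
}

#' Apply genotyping noise
#'
#' Each call is independently set missing with probability `missingRate`;
#' each remaining homozygote is flipped to a heterozygote with probability
#' `hetErrorRate`.  Rates of zero return the input unchanged.
#'
#' @param x A [GenotypeData] object.
#' @param missingRate,hetErrorRate Probabilities in `[0,1]`.
#' @param seed Integer seed.
#' @return A [GenotypeData] object.
#' @export
applyNoise <- function(x, missingRate = 0, hetErrorRate = 0, seed) {
    stopifnot(missingRate >= 0, missingRate <= 1,
              hetErrorRate >= 0, hetErrorRate <= 1)
    if (missingRate == 0 && hetErrorRate == 0) return(x)
    g <- genotypeCalls(x)
    .withSeed(seed, {
        if (missingRate > 0)
            g[runif(length(g)) < missingRate] <- NA_integer_
        if (hetErrorRate > 0) {
            hom <- !is.na(g) & g != 1L
            flip <- hom & runif(length(g)) < hetErrorRate
            g[flip] <- 1L
        }
    })
    GenotypeData(g, markerInfo(x), sampleInfo(x), sort = FALSE)
}

#' Write a simulated dataset to files
#'
#' Writes PLINK binary (`<prefix>.bed/.bim/.fam`), the planted-segment truth
#' as TSV (`<prefix>.truth.tsv`) and realized parameters as JSON
#' (`<prefix>.params.json`).
#'
#' @param config A [simConfig()].
#' @param prefix Output prefix.
#' @param segments Optional segment spec passed to
#'   [plantAutozygousSegments()].
#' @return Invisibly, the list from [simulatePopulations()] (after
#'   planting).
#' @export
simulateToFiles <- function(config, prefix, segments = NULL) {
    sim <- simulatePopulations(config)
    if (!is.null(segments)) {
        sim <- plantAutozygousSegments(sim$geno, segments,
                                       seed = .splitSeed(config$seed, 3L),
                                       truth = sim$truth)
    }
    writePlinkBinary(sim$geno, prefix)
    utils::write.table(sim$truth$plantedSegments,
                       paste0(prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(seed = config$seed,
             populations = config$populationNames,
             n_per_population = config$nPerPopulation,
             per_population_F = as.list(sim$truth$perPopulationF),
             missing_rate = config$missingRate,
             het_error_rate = config$hetErrorRate),
        paste0(prefix, ".params.json"), auto_unbox = TRUE, digits = NA)
    invisible(sim)
}
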