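## End-to-end orchestration: qc -> prune -> roh -> inbreeding ->
## fst/pca/ibd -> islands -> annotation, from one YAML (or list) config,
## writing plain TSV/BED/JSON stage outputs plus a run manifest.  Stage
## parameter defaults are the chip-analysis values used throughout the
## package (call rate 0.90; 50-SNP window / step 5 / r2 0.5; ROH 1 Mb /
## 60 SNPs / zero het / zero missing / 1 Mb gap; outlier threshold 0.5;
## top 1% occurrence; 1 Mb island merge gap).

.defaultRunConfig <- function() {
    list(input = list(plink_prefix = NULL, ped = NULL, map = NULL,
                      vcf = NULL, pop_file = NULL),
         output_dir = "rohscan_out",
         seed = 1L,
         qc = list(sample_cr_min = 0.90, marker_cr_min = 0.90),
         prune = list(window_snps = 50, step_snps = 5, r2_max = 0.5),
         roh = list(min_length_bp = 1e6, min_snps = 60, max_gap_bp = 1e6),
         inbreeding = list(l_aut_bp = NULL, freq_basis = "population"),
         fst = list(estimator = "wright", n_boot = 200,
                    outlier_threshold = 0.5),
         pca = list(n_components = 10),
         ibd = list(enabled = TRUE),
         islands = list(top_fraction = 0.01, merge_gap_bp = 1e6),
         annotation = list(genes = NULL, qtl = NULL))
}

.mergeConfig <- function(defaults, user, path = "") {
    for (key in names(user)) {
        full <- paste0(path, key)
        if (!key %in% names(defaults))
            stop("unknown config key: ", full)
        if (is.list(defaults[[key]]) && !is.null(user[[key]]))
            defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                            paste0(full, "."))
        else defaults[[key]] <- user[[key]]
    }
    defaults
}

.writeTsv <- function(d, path)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Loads genotypes, applies QC and LD pruning, detects runs of
#' homozygosity, computes inbreeding coefficients, pairwise/per-marker
#' Fixation Index, PCA and IBD/GRM relatedness, builds per-population ROH
#' islands, optionally annotates them with gene/QTL interval files, and
#' writes every stage's tables plus a JSON manifest (package version,
#' parameters, input checksums, seed) to `output_dir`.  Deterministic
#' stages re-run bit-identically for the same config and inputs.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Unknown keys are rejected.  See the package vignette for the schema.
#' @param geno Optionally, a [GenotypeData] object overriding
#'   `config$input`.
#' @return Invisibly, a list with the main in-memory results
#'   (`qc`, `segments`, `summary`, `inbreeding`, `fst`, `pca`, `islands`,
#'   `manifest`).
#' @export
runPipeline <- function(config, geno = NULL) {
    user <- if (is.character(config)) yaml::read_yaml(config) else config
    cfg <- .mergeConfig(.defaultRunConfig(), user)
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    outp <- function(f) file.path(cfg$output_dir, f)
    checksums <- list()
    if (is.null(geno)) {
        inp <- cfg$input
        if (!is.null(inp$plink_prefix)) {
            files <- paste0(inp$plink_prefix, c(".bed", ".bim", ".fam"))
            geno <- readPlinkBinary(files[1], files[2], files[3])
        } else if (!is.null(inp$ped)) {
            files <- c(inp$ped, inp$map)
            geno <- readPlinkText(inp$ped, inp$map)
        } else if (!is.null(inp$vcf)) {
            files <- inp$vcf
            geno <- readGenotypeVcf(inp$vcf, inp$pop_file)
        } else stop("config$input must name plink_prefix, ped/map or vcf")
        checksums <- as.list(tools::md5sum(files))
    }
    ## QC
    qc <- qcFilter(geno, cfg$qc$sample_cr_min, cfg$qc$marker_cr_min)
    gd <- qc$geno
    jsonlite::write_json(qc$report[c("n_samples_in", "n_samples_out",
                                     "n_markers_in", "n_markers_out")],
                         outp("qc_report.json"), auto_unbox = TRUE)
    .writeTsv(qc$report$removed_markers, outp("qc_removed_markers.tsv"))
    .writeTsv(qc$report$removed_samples, outp("qc_removed_samples.tsv"))
    ## LD pruning (structure analyses only; never before ROH)
    keep <- ldPrune(gd, cfg$prune$window_snps, cfg$prune$step_snps,
                    cfg$prune$r2_max)
    writeLines(keep, outp("pruned_keeplist.txt"))
    pruned <- gd[markerInfo(gd)$marker_id %in% keep, ]
    ## ROH on the unpruned QC'd set
    seg <- detectRoh(gd, cfg$roh$min_length_bp, cfg$roh$min_snps,
                     maxGapBp = cfg$roh$max_gap_bp)
    .writeTsv(seg, outp("roh_segments.tsv"))
    writeRohBed(seg, outp("roh_segments.bed"))
    summ <- summarizeRoh(seg, sampleInfo(gd))
    .writeTsv(summ$perPopulation, outp("roh_summary_population.tsv"))
    .writeTsv(summ$perIndividual, outp("roh_summary_individual.tsv"))
    .writeTsv(summ$perClass, outp("roh_summary_class.tsv"))
    .writeTsv(chromosomeCoverage(seg, gd), outp("roh_chromosomes.tsv"))
    ## inbreeding
    lAut <- if (is.null(cfg$inbreeding$l_aut_bp))
        coveredAutosomeLength(gd, autosomes = NULL)
    else cfg$inbreeding$l_aut_bp
    froh <- frohRecords(seg, sampleInfo(gd), lAut,
                        chromosomes = unique(markerInfo(gd)$chromosome))
    fx <- excessHomozygosityF(gd, freqBasis = cfg$inbreeding$freq_basis)
    .writeTsv(merge(fx, froh$records[, c("sample_id", "l_roh_bp", "f_roh")],
                    by = "sample_id"), outp("inbreeding.tsv"))
    .writeTsv(inbreedingSummary(fx, froh$records),
              outp("inbreeding_summary.tsv"))
    reg <- tryCatch(fVsFrohRegression(fx, froh$records),
                    error = function(e) NULL)
    if (!is.null(reg)) .writeTsv(reg, outp("f_vs_froh_regression.tsv"))
    ## differentiation: overall Fst on pruned set, marker scan on full set
    fstP <- pairwiseFstAll(pruned, estimator = cfg$fst$estimator,
                           nBoot = cfg$fst$n_boot, seed = cfg$seed)
    .writeTsv(fstP, outp("fst_pairwise.tsv"))
    pops <- unique(populations(gd))
    outliers <- list()
    for (pr in utils::combn(pops, 2, simplify = FALSE)) {
        fr <- pairwiseFst(gd, pr[1], pr[2], estimator = cfg$fst$estimator,
                          nBoot = 0)
        ol <- fstOutlierScan(fr, cfg$fst$outlier_threshold)
        if (nrow(ol)) ol$pair <- paste(pr, collapse = "_")
        outliers[[paste(pr, collapse = "_")]] <- ol
    }
    .writeTsv(do.call(rbind, outliers), outp("fst_outliers.tsv"))
    ## PCA + relatedness on the pruned set
    pca <- pcaGenotypes(pruned, nComponents = cfg$pca$n_components)
    .writeTsv(data.frame(sample_id = rownames(pca$scores),
                         population = populations(pruned), pca$scores),
              outp("pca_scores.tsv"))
    .writeTsv(data.frame(component = seq_along(pca$eigenvalues),
                         eigenvalue = pca$eigenvalues),
              outp("pca_eigenvalues.tsv"))
    rel <- NULL
    if (isTRUE(cfg$ibd$enabled)) {
        rel <- relatedness(pruned)
        .writeTsv(rel$ibd, outp("ibd.tsv"))
        .writeTsv(rel$blockMeans, outp("grm_block_means.tsv"))
    }
    ## islands per population (+ optional annotation)
    genes <- if (!is.null(cfg$annotation$genes))
        readFeatures(cfg$annotation$genes) else NULL
    qtl <- if (!is.null(cfg$annotation$qtl))
        readFeatures(cfg$annotation$qtl) else NULL
    islandsByPop <- list(); genesByPop <- list()
    for (pp in pops) {
        prof <- occurrenceProfile(seg, gd, pp)
        .writeTsv(prof, outp(paste0("occurrence_", pp, ".tsv")))
        top <- suppressWarnings(topSnpThreshold(prof,
                                                cfg$islands$top_fraction))
        isl <- buildIslands(top$topSnps, cfg$islands$merge_gap_bp, pp)
        islandsByPop[[pp]] <- isl
        if (!is.null(genes)) {
            ann <- intersectAnnotation(isl, genes)
            isl <- ann$annotated
            genesByPop[[pp]] <- unique(ann$hits$name)
        }
        if (!is.null(qtl)) {
            annQ <- intersectAnnotation(islandsByPop[[pp]], qtl)
            .writeTsv(annQ$classCounts, outp(paste0("qtl_classes_", pp,
                                                    ".tsv")))
        }
        .writeTsv(isl, outp(paste0("islands_", pp, ".tsv")))
        writeIslandsBed(islandsByPop[[pp]],
                        outp(paste0("islands_", pp, ".bed")))
    }
    sharing <- NULL
    if (length(islandsByPop) >= 2) {
        sharing <- crossPopulationSharing(
            islandsByPop,
            if (length(genesByPop)) genesByPop else NULL)
        .writeTsv(sharing$sharedRegions, outp("islands_shared.tsv"))
        if (!is.null(sharing$vennCounts))
            .writeTsv(sharing$vennCounts, outp("gene_venn.tsv"))
    }
    manifest <- list(package = "rohscan",
                     version = as.character(utils::packageVersion("rohscan")),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     seed = cfg$seed,
                     parameters = cfg[setdiff(names(cfg),
                                              c("input", "output_dir"))],
                     input_md5 = checksums,
                     outputs = list.files(cfg$output_dir))
    jsonlite::write_json(manifest, outp("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(qc = qc$report, segments = seg, summary = summ,
                   inbreeding = list(froh = froh, f = fx),
                   fst = fstP, pca = pca, islands = islandsByPop,
                   sharing = sharing, relatedness = rel,
                   manifest = manifest))
}
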