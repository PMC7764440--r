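## PLINK PED/MAP + BED/BIM/FAM (SNP-major) + VCF 4.x (GT only) readers and
## writers.  Codes count copies of allele2; for text PED the allele1/allele2
## assignment is first-seen order across samples, persisted to BIM on write.

.readMapFile <- function(mapPath) {
    mp <- utils::read.table(mapPath, header = FALSE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(mp) == 3L) mp <- cbind(mp[, 1:2], "0", mp[, 3])
    if (ncol(mp) < 4L)
        stop("MAP file must have 3 or 4 columns, found ", ncol(mp))
    data.frame(marker_id = mp[[2]], chromosome = mp[[1]],
               position_bp = as.integer(mp[[4]]),
               stringsAsFactors = FALSE)
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Allele pairs are recoded to copies of `allele2`, where `allele1` is the
#' first non-missing allele observed at each marker (scanning samples in
#' order, then the two alleles of a pair); `"0 0"` (or any half-missing pair)
#' becomes `NA`.  Markers are returned sorted by (chromosome, position);
#' sample order is preserved.  Population labels are taken from the PED
#' family column.
#'
#' @param pedPath,mapPath Paths to the `.ped` and `.map` files.
#' @return A [GenotypeData] object.
#' @export
readPlinkText <- function(pedPath, mapPath) {
    map <- .readMapFile(mapPath)
    m <- nrow(map)
    if (m == 0L) stop("MAP file contains no markers")
    lines <- readLines(pedPath)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("PED file contains no samples")
    tok <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(tok)
    want <- 6L + 2L * m
    bad <- which(nf != want)
    if (length(bad))
        stop("PED line ", bad[1], " has ", nf[bad[1]], " fields, expected ",
             want, " (6 + 2 per marker); PED/MAP mismatch or ragged line")
    tok <- do.call(rbind, tok)
    n <- nrow(tok)
    si <- data.frame(sample_id = tok[, 2], population = tok[, 1],
                     stringsAsFactors = FALSE)
    a1m <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
    a2m <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
    calls <- matrix(NA_integer_, nrow = n, ncol = m)
    allele1 <- allele2 <- character(m)
    for (j in seq_len(m)) {
        pair <- as.vector(rbind(a1m[, j], a2m[, j]))   # sample-major order
        seen <- unique(pair[pair != "0"])
        if (length(seen) > 2L)
            stop("marker ", map$marker_id[j], " has >2 alleles: ",
                 paste(seen, collapse = ","))
        A1 <- if (length(seen) >= 1L) seen[1] else "0"
        A2 <- if (length(seen) == 2L) seen[2] else "0"
        miss <- a1m[, j] == "0" | a2m[, j] == "0"
        code <- (a1m[, j] == A2) + (a2m[, j] == A2)
        code[miss] <- NA_integer_
        calls[, j] <- as.integer(code)
        allele1[j] <- A1; allele2[j] <- A2
    }
    map$allele1 <- allele1
    map$allele2 <- allele2
    GenotypeData(t(calls), map, si)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param x A [GenotypeData] object.
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
writePlinkText <- function(x, prefix) {
    mi <- markerInfo(x)
    utils::write.table(
        data.frame(mi$chromosome, mi$marker_id, 0L, mi$position_bp),
        paste0(prefix, ".map"), quote = FALSE, sep = "\t",
        row.names = FALSE, col.names = FALSE)
    g <- genotypeCalls(x)                      # markers x samples
    si <- sampleInfo(x)
    a1 <- mi$allele1; a2 <- mi$allele2
    con <- file(paste0(prefix, ".ped"), "w")
    on.exit(close(con))
    for (i in seq_len(ncol(g))) {
        gi <- g[, i]
        left <- ifelse(is.na(gi), "0", ifelse(gi == 2L, a2, a1))
        right <- ifelse(is.na(gi), "0", ifelse(gi == 0L, a1, a2))
        cat(si$population[i], si$sample_id[i], "0", "0", "0", "-9",
            rbind(left, right), file = con, sep = " ")
        cat("\n", file = con)
    }
    invisible(prefix)
}

## 2-bit PLINK codes: 00 hom A1 (0), 01 missing (NA), 10 het (1), 11 hom A2 (2)
.bedDecodeTable <- function() {
    v <- c(0L, NA_integer_, 1L, 2L)
    b <- 0:255
    cbind(v[bitwAnd(b, 3L) + 1L],
          v[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
          v[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
          v[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
}

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' Requires the standard magic bytes `0x6C 0x1B` and SNP-major mode
#' (`0x01`).  Same recoding contract as [readPlinkText()]: codes count
#' copies of the BIM allele2 column... note PLINK's BIM stores A1 then A2 and
#' the 2-bit code 00 means homozygous A1.  Population labels come from the
#' FAM family column.
#'
#' @param bedPath Path to the `.bed` file, or a prefix if `bimPath`/`famPath`
#'   are derived.
#' @param bimPath,famPath Paths to `.bim`/`.fam`; default derived from
#'   `bedPath` by extension replacement.
#' @return A [GenotypeData] object.
#' @export
readPlinkBinary <- function(bedPath,
                            bimPath = sub("\\.bed$", ".bim", bedPath),
                            famPath = sub("\\.bed$", ".fam", bedPath)) {
    if (file.size(bimPath) == 0) stop("BIM file contains no markers")
    if (file.size(famPath) == 0) stop("FAM file contains no samples")
    fam <- utils::read.table(famPath, header = FALSE,
                             colClasses = "character")
    bim <- utils::read.table(bimPath, header = FALSE,
                             colClasses = "character")
    if (ncol(bim) < 6L) stop("BIM file must have 6 columns")
    n <- nrow(fam); m <- nrow(bim)
    if (m == 0L) stop("BIM file contains no markers")
    if (n == 0L) stop("FAM file contains no samples")
    raw <- readBin(bedPath, "raw", n = file.size(bedPath))
    if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
        stop("not a PLINK BED file (bad magic bytes)")
    if (raw[3] != as.raw(0x01))
        stop("only SNP-major BED files are supported")
    bpm <- ceiling(n / 4)                       # bytes per marker
    if (length(raw) != 3L + m * bpm)
        stop("BED file truncated or inconsistent with BIM/FAM: expected ",
             3 + m * bpm, " bytes, found ", length(raw))
    body <- as.integer(raw[-(1:3)])
    lut <- .bedDecodeTable()
    ## bytes for marker j are rows (j-1)*bpm + 1 .. j*bpm
    bytes <- matrix(body, nrow = bpm)           # bpm x m, column = marker
    calls <- matrix(NA_integer_, nrow = m, ncol = n)
    for (k in seq_len(4L)) {
        sidx <- seq(k, by = 4L, length.out = bpm)
        sidx <- sidx[sidx <= n]
        if (!length(sidx)) next
        rows <- seq_along(sidx)
        calls[, sidx] <- t(matrix(lut[bytes[rows, , drop = FALSE] + 1L, k],
                                  nrow = length(rows)))
    }
    map <- data.frame(marker_id = bim[[2]], chromosome = bim[[1]],
                      position_bp = as.integer(bim[[4]]),
                      allele1 = bim[[5]], allele2 = bim[[6]],
                      stringsAsFactors = FALSE)
    si <- data.frame(sample_id = fam[[2]], population = fam[[1]],
                     stringsAsFactors = FALSE)
    GenotypeData(calls, map, si)
}

#' Write PLINK binary genotypes (BED/BIM/FAM)
#'
#' Writes a SNP-major BED/BIM/FAM triple readable by [readPlinkBinary()] and
#' by PLINK itself.  Population labels are persisted in the FAM family
#' column; marker order is preserved.
#'
#' @param x A [GenotypeData] object.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
writePlinkBinary <- function(x, prefix) {
    g <- genotypeCalls(x)                       # markers x samples
    m <- nrow(g); n <- ncol(g)
    mi <- markerInfo(x); si <- sampleInfo(x)
    utils::write.table(
        data.frame(mi$chromosome, mi$marker_id, 0L, mi$position_bp,
                   mi$allele1, mi$allele2),
        paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
        row.names = FALSE, col.names = FALSE)
    utils::write.table(
        data.frame(si$population, si$sample_id, 0L, 0L, 0L, -9L),
        paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
        row.names = FALSE, col.names = FALSE)
    ## 2-bit values: 0->0, NA->1, 1->2, 2->3
    v <- matrix(0L, nrow = m, ncol = n)
    v[is.na(g)] <- 1L; v[!is.na(g) & g == 1L] <- 2L
    v[!is.na(g) & g == 2L] <- 3L
    bpm <- ceiling(n / 4)
    pad <- bpm * 4L - n
    if (pad > 0L) v <- cbind(v, matrix(0L, nrow = m, ncol = pad))
    bytes <- matrix(0L, nrow = m, ncol = bpm)
    for (k in 1:4)
        bytes <- bytes + v[, seq(k, by = 4L, length.out = bpm),
                           drop = FALSE] * 4L^(k - 1L)
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(as.vector(t(bytes))), con)  # SNP-major
    invisible(prefix)
}

#' Read genotypes from VCF
#'
#' Maps GT fields `0/0` to 0, `0/1`/`1/0` to 1, `1/1` to 2 and `./.` to
#' `NA` (phased separators accepted).  Multi-allelic sites are skipped with
#' a warning; a missing GT FORMAT is an error.  VCF carries no population
#' field, so labels come from `popFile` (two-column whitespace table:
#' sample_id, population) or default to `"unknown"`.
#'
#' @param vcfPath Path to an (uncompressed or bgzipped) VCF.
#' @param popFile Optional path to a sample-to-population table.
#' @return A [GenotypeData] object.
#' @export
readGenotypeVcf <- function(vcfPath, popFile = NULL) {
    v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    if (!"FORMAT" %in% colnames(v@gt) || !any(grepl("GT", v@gt[, "FORMAT"])))
        stop("VCF has no GT field")
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
        warning(sum(multi), " multi-allelic site(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                       dimnames = list(NULL, colnames(v@gt)[-1]))
    keep <- !multi
    gt <- gt[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]
    if (!nrow(fix)) stop("no bi-allelic sites in VCF")
    code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    gtn <- gsub("\\|", "/", gt)
    code[gtn %in% "0/0"] <- 0L
    code[gtn %in% c("0/1", "1/0")] <- 1L
    code[gtn %in% "1/1"] <- 2L
    alt <- fix[, "ALT"]; alt[is.na(alt) | alt == "."] <- "0"
    ids <- fix[, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
    map <- data.frame(marker_id = ids, chromosome = fix[, "CHROM"],
                      position_bp = as.integer(fix[, "POS"]),
                      allele1 = fix[, "REF"], allele2 = alt,
                      stringsAsFactors = FALSE)
    pops <- rep("unknown", ncol(gt))
    if (!is.null(popFile)) {
        pf <- utils::read.table(popFile, header = FALSE,
                                colClasses = "character")
        pops <- pf[[2]][match(colnames(gt), pf[[1]])]
    }
    si <- data.frame(sample_id = colnames(gt), population = pops,
                     stringsAsFactors = FALSE)
    GenotypeData(code, map, si)
}

#' Write genotypes to VCF
#'
#' Minimal VCF 4.2 with GT only; REF = allele1, ALT = allele2 (`.` when the
#' marker is monomorphic with unknown second allele).
#'
#' @param x A [GenotypeData] object.
#' @param vcfPath Output path.
#' @return The path, invisibly.
#' @export
writeGenotypeVcf <- function(x, vcfPath) {
    mi <- markerInfo(x); si <- sampleInfo(x)
    g <- genotypeCalls(x)
    gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
    ref <- ifelse(mi$allele1 == "0", "N", mi$allele1)
    alt <- ifelse(mi$allele2 == "0", ".", mi$allele2)
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", si$sample_id), collapse = "\t"))
    body <- cbind(mi$chromosome, mi$position_bp, mi$marker_id, ref, alt,
                  ".", ".", ".", "GT", gt)
    writeLines(c(header, apply(body, 1, paste, collapse = "\t")), vcfPath)
    invisible(vcfPath)
}
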