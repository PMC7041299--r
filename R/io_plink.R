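# PLINK genotype I/O.
#
# Supports the binary .bed/.bim/.fam triple (SNP-major bed, magic bytes
# 0x6c 0x1b 0x01) and the text .ped/.map pair. Dosages are re-oriented to
# count the minor allele observed in the loaded cohort.

# 2-bit PLINK codes (SNP-major): 00 = hom A1, 01 = missing, 10 = het,
# 11 = hom A2. A1 dosage per code:
.plink_code_to_dosage <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)

# byte -> 4 genotype codes, sample order = low bits first
.plink_byte_lookup <- function() {
  b <- 0:255
  cbind(
    bitwAnd(b, 3L),
    bitwAnd(bitwShiftR(b, 2L), 3L),
    bitwAnd(bitwShiftR(b, 4L), 3L),
    bitwAnd(bitwShiftR(b, 6L), 3L)
  )
}

#' Read genotypes from PLINK files
#'
#' Accepts either a binary `.bed/.bim/.fam` triple or a text `.ped/.map`
#' pair; `prefix` is the common path without extension. The `.fam`/`.ped`
#' phenotype column (1 = control, 2 = case, 0/-9 = missing) is returned as a
#' [phenotype()] when both classes are present, otherwise `NULL`.
#'
#' @param prefix Path prefix of the PLINK fileset.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `phenotype` (a [phenotype()] or `NULL`).
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix)
  } else {
    stop("no PLINK fileset at prefix: ", prefix, call. = FALSE)
  }
}

read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f, call. = FALSE)
  }
  bim_tab <- utils::read.table(bim, stringsAsFactors = FALSE,
                               col.names = c("chrom", "snp_id", "cm", "pos",
                                             "a1", "a2"),
                               colClasses = c("character", "character",
                                              "numeric", "integer",
                                              "character", "character"))
  fam_tab <- utils::read.table(fam, stringsAsFactors = FALSE,
                               col.names = c("fid", "iid", "pid", "mid",
                                             "sex", "pheno"))
  n_snps <- nrow(bim_tab)
  n_samples <- nrow(fam_tab)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK .bed file: ", bed, call. = FALSE)
  }
  bytes_per_snp <- ceiling(n_samples / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != n_snps * bytes_per_snp) {
    stop(sprintf(
      ".bed payload (%d bytes) inconsistent with .bim (%d SNPs) x .fam (%d samples)",
      length(payload), n_snps, n_samples
    ), call. = FALSE)
  }

  lut <- .plink_byte_lookup()
  codes <- lut[as.integer(payload) + 1L, , drop = FALSE]  # (bytes) x 4
  # rows of `codes` follow byte order: all bytes of SNP 1, then SNP 2, ...
  codes <- matrix(t(codes), nrow = 4L * bytes_per_snp)    # per-SNP columns
  codes <- codes[seq_len(n_samples), , drop = FALSE]      # drop pad genotypes
  dos <- matrix(.plink_code_to_dosage[as.character(codes)],
                nrow = n_samples, ncol = n_snps)

  snps <- data.frame(
    snp_id = bim_tab$snp_id, chrom = bim_tab$chrom, pos = bim_tab$pos,
    allele_major = bim_tab$a2, allele_minor = bim_tab$a1,
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(dos, snps, sample_ids = fam_tab$iid)
  phen <- tryCatch(fam_to_phenotype(fam_tab$pheno), error = function(e) NULL)
  list(genotypes = gm, phenotype = phen)
}

read_plink_ped <- function(prefix) {
  ped <- paste0(prefix, ".ped")
  map <- paste0(prefix, ".map")
  if (!file.exists(map)) stop("missing PLINK file: ", map, call. = FALSE)
  map_tab <- utils::read.table(map, stringsAsFactors = FALSE,
                               col.names = c("chrom", "snp_id", "cm", "pos"),
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  lines <- readLines(ped)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty .ped file: ", ped, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_snps <- nrow(map_tab)
  expected <- 6L + 2L * n_snps
  if (any(lengths(fields) != expected)) {
    stop(sprintf(".ped rows do not match .map (%d SNPs expected)", n_snps),
         call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  iid <- mat[, 2L]
  pheno <- suppressWarnings(as.integer(mat[, 6L]))
  alleles <- mat[, -(1:6), drop = FALSE]
  n_samples <- nrow(mat)

  dos <- matrix(NA_integer_, n_samples, n_snps)
  major <- minor <- character(n_snps)
  for (j in seq_len(n_snps)) {
    a <- alleles[, 2L * j - 1L]
    b <- alleles[, 2L * j]
    obs <- c(a, b)
    obs <- obs[obs != "0"]
    lev <- names(sort(table(obs), decreasing = TRUE))
    if (length(lev) == 0L) lev <- c("A", "a")
    if (length(lev) == 1L) lev <- c(lev, if (lev == "A") "a" else "A")
    major[j] <- lev[1L]
    minor[j] <- lev[2L]
    d <- (a == minor[j]) + (b == minor[j])
    d[a == "0" | b == "0"] <- NA_integer_
    dos[, j] <- as.integer(d)
  }
  snps <- data.frame(
    snp_id = map_tab$snp_id, chrom = map_tab$chrom, pos = map_tab$pos,
    allele_major = major, allele_minor = minor, stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(dos, snps, sample_ids = iid)
  phen <- tryCatch(fam_to_phenotype(pheno), error = function(e) NULL)
  list(genotypes = gm, phenotype = phen)
}

#' Write genotypes as a PLINK binary fileset
#'
#' Writes `.bed` (SNP-major), `.bim` and `.fam` files that round-trip exactly
#' through [read_plink()]: dosages, SNP ids and phenotype labels are
#' recovered unchanged. The minor allele is written as PLINK allele A1.
#'
#' @param gm A [genotype_matrix()].
#' @param phen A [phenotype()] aligned with `gm`, or `NULL` (phenotype column
#'   written as missing).
#' @param prefix Output path prefix (directories must exist).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, phen, prefix) {
  if (!inherits(gm, "genotype_matrix")) stop("gm must be a genotype_matrix",
                                             call. = FALSE)
  n_samples <- nrow(gm$dosages)
  n_snps <- ncol(gm$dosages)
  if (n_samples == 0L || length(gm$sample_ids) == 0L) {
    stop("cannot write PLINK files for an empty sample list", call. = FALSE)
  }
  if (!is.null(phen)) {
    if (!inherits(phen, "phenotype")) stop("phen must be a phenotype",
                                           call. = FALSE)
    if (length(phen$labels) != n_samples) {
      stop("phenotype length does not match sample count", call. = FALSE)
    }
  }

  pheno_code <- if (is.null(phen)) rep(-9L, n_samples) else {
    ifelse(is.na(phen$labels), -9L, ifelse(phen$labels == 1L, 2L, 1L))
  }
  fam <- data.frame(gm$sample_ids, gm$sample_ids, 0L, 0L, 0L, pheno_code)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gm$snps$chrom, gm$snps$snp_id, 0, gm$snps$pos,
                    gm$snps$allele_minor, gm$snps$allele_major)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  # dosage of A1 (minor) -> 2-bit code
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2L] <- 0L
    out[!is.na(d) & d == 1L] <- 2L
    out[!is.na(d) & d == 0L] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n_samples / 4)
  pad <- 4L * bytes_per_snp - n_samples
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  shifts <- c(1L, 4L, 16L, 64L)  # 2-bit positions within a byte
  for (j in seq_len(n_snps)) {
    codes <- c(code_of(gm$dosages[, j]), rep(3L, pad))
    m <- matrix(codes, nrow = 4L)
    bytes <- as.integer(colSums(m * shifts))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
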