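#' Read genotypes from a VCF file
#'
#' Loads the GT field of a VCF 4.x file into the internal minor-allele dosage
#' representation. Only biallelic records are used; multiallelic records are
#' skipped with a warning. Allele orientation (which allele is "minor") is
#' recomputed from the loaded samples, not taken from REF/ALT order, so a
#' record whose ALT allele is the majority allele is flipped.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path, call. = FALSE)

  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi)) {
    warning(sprintf("skipping %d multiallelic/invalid VCF record(s)", sum(multi)))
  }
  keep <- which(!multi)
  if (!length(keep)) stop("VCF has zero biallelic records: ", path, call. = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # count ALT alleles per genotype string ("0/1", "1|1", "./.", ...)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  alt_count <- (a1 == "1") + (a2 == "1")
  alt_count[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  # haploid-style single-field GT (rare in input scope): treat as missing
  alt_count[nchar(gt) < 3L & !is.na(gt)] <- NA_integer_

  dos <- t(matrix(as.integer(alt_count), nrow = nrow(gt),
                  dimnames = dimnames(gt)))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf(
    "%s:%s", fix$CHROM[is.na(ids) | ids == "."], fix$POS[is.na(ids) | ids == "."]
  )
  snps <- data.frame(
    snp_id = ids,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    allele_major = fix$REF,   # reoriented by genotype_matrix() if ALT is major
    allele_minor = fix$ALT,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, snps, sample_ids = colnames(gt))
}
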