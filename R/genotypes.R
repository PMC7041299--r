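#' Genotype matrix container
#'
#' Holds an `n_samples x n_snps` minor-allele dosage matrix together with
#' per-SNP metadata. Dosages count copies of the minor allele, so the three
#' genotypes AA, Aa and aa (with `a` the minor allele) map to 0, 1 and 2.
#' Missing genotypes are stored as `NA`.
#'
#' @param dosages Integer matrix, samples in rows, SNPs in columns, values in
#'   `{0, 1, 2, NA}`.
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `allele_major`, `allele_minor`; one row per column of `dosages`.
#'   A `maf` column is (re)computed from the data.
#' @param sample_ids Character vector of sample identifiers.
#' @param orient If `TRUE` (default), columns whose empirical allele frequency
#'   exceeds 0.5 are flipped (`dosage <- 2 - dosage`, alleles swapped) so the
#'   dosage always counts the minor allele in the loaded cohort. Ties at 0.5
#'   keep the input orientation.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snps`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, snps, sample_ids = rownames(dosages),
                            orient = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) < 2L) {
    stop("genotype_matrix needs at least 2 samples", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample%d", seq_len(nrow(dosages)))
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "allele_major", "allele_minor")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols)) {
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(snps) != ncol(dosages)) {
    stop("snps table rows must match dosage columns", call. = FALSE)
  }
  if (any(snps$pos < 1L)) stop("SNP positions must be >= 1", call. = FALSE)
  bad <- !(dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("dosages must be in {0,1,2,NA}", call. = FALSE)

  if (orient) {
    freq <- colMeans(dosages, na.rm = TRUE) / 2
    flip <- which(!is.na(freq) & freq > 0.5)
    if (length(flip)) {
      dosages[, flip] <- 2L - dosages[, flip]
      tmp <- snps$allele_major[flip]
      snps$allele_major[flip] <- snps$allele_minor[flip]
      snps$allele_minor[flip] <- tmp
    }
  }
  snps$maf <- colMeans(dosages, na.rm = TRUE) / 2
  snps$maf[is.nan(snps$maf)] <- 0
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snps$snp_id
  structure(
    list(dosages = dosages, snps = snps, sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param samples Row (sample) indices, or `NULL` to keep all.
#' @param snps Column (SNP) indices, or `NULL` to keep all.
#' @return A `genotype_matrix` restricted to the requested samples/SNPs.
#'   Allele orientation is preserved (not recomputed), so dosages remain
#'   comparable to the parent object.
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  samples <- samples %||% seq_len(nrow(gm$dosages))
  snps <- snps %||% seq_len(ncol(gm$dosages))
  dos <- gm$dosages[samples, snps, drop = FALSE]
  tab <- gm$snps[snps, , drop = FALSE]
  tab$maf <- colMeans(dos, na.rm = TRUE) / 2
  tab$maf[is.nan(tab$maf)] <- 0
  structure(
    list(dosages = dos, snps = tab, sample_ids = gm$sample_ids[samples]),
    class = "genotype_matrix"
  )
}

#' Binary phenotype
#'
#' Case/control labels coded `+1` (case) and `-1` (control), aligned with the
#' sample order of the accompanying genotype matrix.
#'
#' @param labels Vector coercible to integer with values in `{-1, 1}` (or
#'   `NA` for missing phenotype).
#' @param positive_label_name Display name of the `+1` class.
#' @return An object of class `phenotype`.
#' @export
phenotype <- function(labels, positive_label_name = "case") {
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L) | is.na(labels))) {
    stop("phenotype labels must be -1 or +1 (NA allowed)", call. = FALSE)
  }
  ok <- labels[!is.na(labels)]
  if (!any(ok == 1L) || !any(ok == -1L)) {
    stop("phenotype needs at least one sample of each class", call. = FALSE)
  }
  structure(
    list(labels = labels, positive_label_name = positive_label_name),
    class = "phenotype"
  )
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf(
    "phenotype: %d cases (+1, '%s'), %d controls (-1), %d missing\n",
    sum(x$labels == 1L, na.rm = TRUE), x$positive_label_name,
    sum(x$labels == -1L, na.rm = TRUE), sum(is.na(x$labels))
  ))
  invisible(x)
}

# PLINK .fam phenotype coding: 1 = control -> -1, 2 = case -> +1,
# 0 / -9 = missing -> NA.
fam_to_phenotype <- function(codes, positive_label_name = "case") {
  codes <- as.integer(codes)
  lab <- rep(NA_integer_, length(codes))
  lab[codes == 1L] <- -1L
  lab[codes == 2L] <- 1L
  phenotype(lab, positive_label_name)
}

#' Read a phenotype table
#'
#' Expects a CSV with columns `sample_id` and `label`; labels may be coded
#' `-1/1`, `0/1` (0 = control) or `1/2` (PLINK convention).
#'
#' @param path CSV file path.
#' @param sample_ids Optional character vector; when given, rows are matched
#'   and ordered to these ids (an error is raised for missing samples).
#' @return A [phenotype()].
#' @export
read_phenotype_csv <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(tab)) || nrow(tab) == 0L) {
    stop("phenotype file needs non-empty columns sample_id,label: ", path,
         call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    m <- match(sample_ids, tab$sample_id)
    if (anyNA(m)) {
      stop("phenotype file is missing sample(s): ",
           paste(utils::head(sample_ids[is.na(m)], 5L), collapse = ", "),
           call. = FALSE)
    }
    tab <- tab[m, , drop = FALSE]
  }
  lab <- as.integer(tab$label)
  vals <- sort(unique(lab[!is.na(lab)]))
  if (identical(vals, c(0L, 1L))) lab <- ifelse(lab == 0L, -1L, 1L)
  if (identical(vals, c(1L, 2L))) lab <- ifelse(lab == 1L, -1L, 1L)
  phenotype(lab)
}
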