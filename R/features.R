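# Two-element combinatorial encoding: one-hot genotype indicators plus
# nine-term pairwise interaction indicators, and the genotype-frequency /
# chi-squared quality filters applied before modeling.

GENOTYPE_LABELS <- c("AA", "Aa", "aa")  # dosage 0, 1, 2 of the minor allele

#' One-hot encode a SNP column
#'
#' @param gm A [genotype_matrix()].
#' @param snp_index Column index.
#' @return An integer `n x 3` matrix with columns (AA, Aa, aa) ordered by
#'   minor-allele dosage; a missing genotype yields an all-zero row.
#' @export
one_hot <- function(gm, snp_index) {
  d <- gm$dosages[, snp_index]
  out <- matrix(0L, nrow = length(d), ncol = 3L,
                dimnames = list(NULL, GENOTYPE_LABELS))
  obs <- which(!is.na(d))
  out[cbind(obs, d[obs] + 1L)] <- 1L
  out
}

#' Nine-term interaction block of two one-hot triplets
#'
#' Column (m, n) is the elementwise product `cols1[, m] * cols2[, n]` for
#' m, n in (AA, Aa, aa); at most one of the nine fires per sample, and none
#' fires when either parent genotype is missing.
#'
#' @param cols1,cols2 `n x 3` one-hot matrices from [one_hot()].
#' @return An integer `n x 9` matrix, columns in lexicographic (m, n) order.
#' @export
interaction_block <- function(cols1, cols2) {
  if (nrow(cols1) != nrow(cols2)) stop("sample dimensions differ", call. = FALSE)
  out <- cols1[, rep(1:3, each = 3L), drop = FALSE] *
    cols2[, rep(1:3, times = 3L), drop = FALSE]
  colnames(out) <- paste(rep(GENOTYPE_LABELS, each = 3L),
                         rep(GENOTYPE_LABELS, times = 3L), sep = "x")
  out
}

new_feature_matrix <- function(values, descriptors) {
  stopifnot(ncol(values) == nrow(descriptors))
  colnames(values) <- descriptors$label
  structure(list(values = values, descriptors = descriptors),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%d single, %d pair)\n",
              nrow(x$values), ncol(x$values),
              sum(x$descriptors$kind == "single"),
              sum(x$descriptors$kind == "pair")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

subset_features <- function(fm, idx) {
  new_feature_matrix(fm$values[, idx, drop = FALSE],
                     fm$descriptors[idx, , drop = FALSE])
}

feature_label <- function(snp1, geno1, snp2 = NA, geno2 = NA) {
  n <- max(length(snp1), length(geno1), length(snp2), length(geno2))
  snp1 <- rep_len(snp1, n)
  geno1 <- rep_len(geno1, n)
  snp2 <- rep_len(snp2, n)
  geno2 <- rep_len(geno2, n)
  ifelse(is.na(snp2), paste0(snp1, "_", geno1),
         paste0(snp1, "_", geno1, ", ", snp2, "_", geno2))
}

single_descriptors <- function(snp_ids, genes) {
  data.frame(
    kind = "single",
    snp1_id = rep(snp_ids, each = 3L),
    genotype1 = rep(GENOTYPE_LABELS, times = length(snp_ids)),
    snp2_id = NA_character_, genotype2 = NA_character_,
    genes1 = rep(genes, each = 3L), genes2 = NA_character_,
    cross_gene = FALSE,
    label = feature_label(rep(snp_ids, each = 3L),
                          rep(GENOTYPE_LABELS, times = length(snp_ids))),
    stringsAsFactors = FALSE
  )
}

pair_descriptors <- function(snp1, genes1, snp2, genes2, cross_gene = FALSE) {
  g1 <- rep(GENOTYPE_LABELS, each = 3L)
  g2 <- rep(GENOTYPE_LABELS, times = 3L)
  data.frame(
    kind = "pair", snp1_id = snp1, genotype1 = g1,
    snp2_id = snp2, genotype2 = g2,
    genes1 = genes1, genes2 = genes2, cross_gene = cross_gene,
    label = feature_label(snp1, g1, snp2, g2),
    stringsAsFactors = FALSE
  )
}

#' Combinatorially encoded design matrix for one gene
#'
#' Builds the 3k single-genotype indicator columns followed by the
#' 9 * k(k-1)/2 pairwise interaction columns over the unordered SNP pairs of
#' the gene. Interaction columns that exactly duplicate one of their parent
#' single columns (which happens when the other SNP is monomorphic on the
#' samples where the parent fires) are dropped with a message, keeping the
#' simpler single-SNP descriptor.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_indices Columns of `gm` belonging to the gene (k >= 1).
#' @param gene_label Gene symbol recorded in the descriptors.
#' @return A `feature_matrix`.
#' @export
gene_feature_matrix <- function(gm, snp_indices, gene_label = NA_character_) {
  k <- length(snp_indices)
  if (k < 1L) stop("gene_feature_matrix needs at least one SNP", call. = FALSE)
  ids <- gm$snps$snp_id[snp_indices]
  singles <- lapply(snp_indices, one_hot, gm = gm)
  values <- do.call(cbind, singles)
  desc <- single_descriptors(ids, gene_label)

  if (k >= 2L) {
    pair_values <- vector("list", k * (k - 1L) / 2L)
    pair_desc <- vector("list", length(pair_values))
    t <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        t <- t + 1L
        pair_values[[t]] <- interaction_block(singles[[i]], singles[[j]])
        pair_desc[[t]] <- pair_descriptors(ids[i], gene_label,
                                           ids[j], gene_label)
      }
    }
    values <- cbind(values, do.call(cbind, pair_values))
    desc <- rbind(desc, do.call(rbind, pair_desc))
  }
  fm <- new_feature_matrix(values, desc)
  drop_parent_duplicates(fm)
}

# Drop pair columns identical to one of their parent single columns.
drop_parent_duplicates <- function(fm) {
  desc <- fm$descriptors
  pair_idx <- which(desc$kind == "pair")
  if (!length(pair_idx)) return(fm)
  single_key <- feature_label(desc$snp1_id, desc$genotype1)
  single_map <- match(
    unique(single_key[desc$kind == "single"]),
    desc$label
  )
  names(single_map) <- desc$label[single_map]
  drop <- logical(ncol(fm$values))
  for (p in pair_idx) {
    for (parent in c(feature_label(desc$snp1_id[p], desc$genotype1[p]),
                     feature_label(desc$snp2_id[p], desc$genotype2[p]))) {
      s <- single_map[parent]
      if (!is.na(s) && identical(fm$values[, p], fm$values[, s])) {
        drop[p] <- TRUE
        break
      }
    }
  }
  if (any(drop)) {
    message(sprintf("dropped %d interaction column(s) duplicating a parent",
                    sum(drop)))
    fm <- subset_features(fm, which(!drop))
  }
  fm
}

#' Genotype frequency of a binary feature column
#'
#' Proportion of samples for which the indicator fires; samples with missing
#' genotypes stay in the denominator (their indicator is 0).
#'
#' @param col Binary 0/1 vector.
#' @return Fraction in `[0, 1]`.
#' @export
genotype_frequency <- function(col) {
  if (!length(col)) stop("empty column", call. = FALSE)
  mean(col)
}

# Vectorized 2x2 Pearson chi-squared p-values (1 df, no continuity
# correction) of each binary column against labels in {-1, +1}.
# Zero-margin (constant) columns get p = 1 by convention.
chi2_pvalues <- function(values, labels) {
  pos <- labels == 1L
  n <- length(labels)
  n_pos <- sum(pos)
  a <- colSums(values[pos, , drop = FALSE])       # feature=1, case
  c1 <- colSums(values) - a                       # feature=1, control
  b <- n_pos - a                                  # feature=0, case
  d <- (n - n_pos) - c1                           # feature=0, control
  row1 <- a + c1
  row0 <- b + d
  num <- n * (a * d - b * c1)^2
  den <- row1 * row0 * as.numeric(n_pos) * (n - n_pos)
  stat <- ifelse(den > 0, num / den, 0)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p[row1 == 0 | row0 == 0] <- 1
  unname(p)
}

#' Chi-squared association p-value of a binary feature
#'
#' Pearson chi-squared on the 2x2 table (feature 0/1 by label -1/+1), one
#' degree of freedom, no continuity correction. A constant feature (zero
#' margin) returns `p = 1`.
#'
#' @param col Binary 0/1 vector.
#' @param phen A [phenotype()].
#' @return p-value in `[0, 1]`.
#' @export
chi2_pvalue <- function(col, phen) {
  if (!any(phen$labels == 1L) || !any(phen$labels == -1L)) {
    stop("both phenotype classes must be present", call. = FALSE)
  }
  chi2_pvalues(matrix(col, ncol = 1L), phen$labels)
}

#' Filter features by genotype frequency and association
#'
#' Retains columns with `genotype_frequency > freq_min` (strict) and
#' chi-squared `p < p_max` (strict). Stage-1 defaults are (0.05, 0.01); the
#' cross-gene stage uses `p_max = 1e-5`. The surviving descriptors gain
#' `freq` and `chi2_p` columns. The operation is idempotent.
#'
#' @param fm A `feature_matrix`.
#' @param phen A [phenotype()].
#' @param freq_min Minimum genotype frequency (exclusive).
#' @param p_max Maximum chi-squared p-value (exclusive).
#' @return The filtered `feature_matrix` (possibly with zero columns).
#' @export
filter_features <- function(fm, phen, freq_min = 0.05, p_max = 0.01) {
  if (ncol(fm$values) == 0L) return(fm)
  freq <- colMeans(fm$values)
  p <- chi2_pvalues(fm$values, phen$labels)
  keep <- which(freq > freq_min & p < p_max)
  out <- subset_features(fm, keep)
  out$descriptors$freq <- freq[keep]
  out$descriptors$chi2_p <- p[keep]
  out
}

# Rebuild indicator columns for a set of descriptors on (possibly new)
# samples of a genotype matrix; used for stage-2 pooling and CV prediction.
features_from_descriptors <- function(gm, desc) {
  col_of <- function(snp_id, geno) {
    j <- match(snp_id, gm$snps$snp_id)
    if (is.na(j)) stop("unknown SNP in descriptor: ", snp_id, call. = FALSE)
    d <- gm$dosages[, j]
    as.integer(!is.na(d) & d == (match(geno, GENOTYPE_LABELS) - 1L))
  }
  values <- matrix(0L, nrow = nrow(gm$dosages), ncol = nrow(desc))
  for (f in seq_len(nrow(desc))) {
    v <- col_of(desc$snp1_id[f], desc$genotype1[f])
    if (desc$kind[f] == "pair") {
      v <- v * col_of(desc$snp2_id[f], desc$genotype2[f])
    }
    values[, f] <- v
  }
  new_feature_matrix(values, desc)
}

#' Export a feature matrix as CSV
#'
#' Columns are named by descriptor display labels (`rs123_Aa`,
#' `rs123_Aa, rs456_aa`).
#'
#' @param fm A `feature_matrix`.
#' @param path Output file.
#' @export
write_features_csv <- function(fm, path) {
  utils::write.csv(as.data.frame(fm$values, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}
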