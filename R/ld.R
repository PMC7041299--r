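# Linkage disequilibrium estimation and LD-based dimensionality reduction.
#
# Haplotype frequencies are estimated from unphased two-locus genotype counts
# by EM over the double-heterozygote phase ambiguity; D' (Lewontin) and r^2
# are derived from them. Highly dependent SNPs (D' and r^2 both above
# threshold) are grouped into blocks and each block is represented by its
# largest-MAF member.

#' EM estimate of two-locus haplotype frequencies
#'
#' Alleles are labelled so that `A`/`B` are the minor alleles of the two
#' SNPs (dosage = count of `A`, resp. `B`). Samples missing either genotype
#' are excluded. All genotype pairs except the double heterozygote determine
#' their two haplotypes; the double heterozygote's phase is resolved by EM,
#' initialized at linkage-equilibrium product frequencies, which makes the
#' result deterministic.
#'
#' @param geno1,geno2 Aligned dosage vectors in `{0,1,2,NA}`.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on haplotype frequency change.
#' @return A list of class `haplotype_freqs`: `p_AB`, `p_Ab`, `p_aB`, `p_ab`,
#'   marginals `p_A`, `p_B`, `n` (samples used) and `degenerate` (`TRUE` when
#'   either locus is monomorphic, leaving LD undefined).
#' @export
em_haplotype_freqs <- function(geno1, geno2, max_iter = 100L, tol = 1e-8) {
  if (length(geno1) != length(geno2)) {
    stop("genotype vectors must be aligned", call. = FALSE)
  }
  ok <- !is.na(geno1) & !is.na(geno2)
  g1 <- geno1[ok]
  g2 <- geno2[ok]
  n <- length(g1)
  if (n == 0L) stop("no complete observations for LD estimation", call. = FALSE)

  p_A <- mean(g1) / 2
  p_B <- mean(g2) / 2
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1)) {
    return(structure(
      list(p_AB = NA_real_, p_Ab = NA_real_, p_aB = NA_real_, p_ab = NA_real_,
           p_A = p_A, p_B = p_B, n = n, degenerate = TRUE),
      class = "haplotype_freqs"
    ))
  }

  # unambiguous haplotype counts; cell (i,j) = #samples with dosages (i,j)
  cnt <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  cnt <- matrix(as.numeric(cnt), 3L, 3L)
  # haplotypes: AB (minor/minor), Ab, aB, ab; counts excluding double hets
  n_dh <- cnt[2L, 2L]
  base_AB <- 2 * cnt[3L, 3L] + cnt[3L, 2L] + cnt[2L, 3L]
  base_Ab <- 2 * cnt[3L, 1L] + cnt[3L, 2L] + cnt[2L, 1L]
  base_aB <- 2 * cnt[1L, 3L] + cnt[1L, 2L] + cnt[2L, 3L]
  base_ab <- 2 * cnt[1L, 1L] + cnt[1L, 2L] + cnt[2L, 1L]
  total <- 2 * n

  p <- c(AB = p_A * p_B, Ab = p_A * (1 - p_B),
         aB = (1 - p_A) * p_B, ab = (1 - p_A) * (1 - p_B))
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between AB/ab and Ab/aB phases
    denom <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
    x <- if (denom > 0) as.numeric(p["AB"] * p["ab"] / denom) else 0.5
    new_p <- c(
      AB = (base_AB + n_dh * x) / total,
      Ab = (base_Ab + n_dh * (1 - x)) / total,
      aB = (base_aB + n_dh * (1 - x)) / total,
      ab = (base_ab + n_dh * x) / total
    )
    delta <- max(abs(new_p - p))
    p <- new_p
    if (delta < tol) break
  }

  structure(
    list(p_AB = as.numeric(p["AB"]), p_Ab = as.numeric(p["Ab"]),
         p_aB = as.numeric(p["aB"]), p_ab = as.numeric(p["ab"]),
         p_A = as.numeric(p["AB"] + p["Ab"]),
         p_B = as.numeric(p["AB"] + p["aB"]),
         n = n, degenerate = FALSE),
    class = "haplotype_freqs"
  )
}

#' Lewontin's D' and r^2 from haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `D' = |D| / D_max` where `D_max` is the tightest
#' marginal bound in the direction of `D`; `r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))`.
#'
#' @param h A `haplotype_freqs` object from [em_haplotype_freqs()].
#' @return A list of class `ld_stats`: `D`, `D_prime`, `r2`.
#' @export
ld_stats <- function(h) {
  if (isTRUE(h$degenerate)) {
    stop("LD undefined: at least one locus is monomorphic", call. = FALSE)
  }
  p_A <- h$p_A
  p_B <- h$p_B
  D <- h$p_AB - p_A * p_B
  D_max <- if (D > 0) {
    min(p_A * (1 - p_B), (1 - p_A) * p_B)
  } else {
    min(p_A * p_B, (1 - p_A) * (1 - p_B))
  }
  D_prime <- if (D_max > 0) abs(D) / D_max else 0
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  structure(list(D = D, D_prime = min(D_prime, 1), r2 = min(r2, 1)),
            class = "ld_stats")
}

#' Collapse SNPs in strong LD into block representatives
#'
#' Within each chromosome, pairs of SNPs at most `window` positions apart in
#' sorted order are linked when both `D' > dprime_thresh` and
#' `r^2 > r2_thresh`; blocks are the transitive closure (union-find) of the
#' linked pairs. Each block is represented by its largest-MAF member (ties:
#' leftmost). Monomorphic SNPs carry no LD information and are never linked.
#'
#' @param gm A [genotype_matrix()] with SNPs sorted by (chrom, pos).
#' @param dprime_thresh,r2_thresh Strict lower thresholds (defaults 0.9).
#' @param window Maximum index separation of tested pairs (default 1000);
#'   set at least to the per-chromosome SNP count for all-pairs behaviour.
#' @return A list: `genotypes` (the reduced [genotype_matrix()], columns in
#'   original order), `blocks` (a `data.frame` with `representative_id`,
#'   `member_ids` comma-joined, and the representative's original column in
#'   `representative_index`), and `kept` (original column indices retained).
#' @export
reduce_by_ld <- function(gm, dprime_thresh = 0.9, r2_thresh = 0.9,
                         window = 1000L) {
  m <- ncol(gm$dosages)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  for (ch in unique(gm$snps$chrom)) {
    idx <- which(gm$snps$chrom == ch)
    idx <- idx[order(gm$snps$pos[idx])]
    k <- length(idx)
    if (k < 2L) next
    for (a in seq_len(k - 1L)) {
      for (b in seq(a + 1L, min(k, a + window))) {
        i <- idx[a]
        j <- idx[b]
        if (find(i) == find(j)) next
        h <- em_haplotype_freqs(gm$dosages[, i], gm$dosages[, j])
        if (isTRUE(h$degenerate)) next
        s <- ld_stats(h)
        if (s$D_prime > dprime_thresh && s$r2 > r2_thresh) union_(i, j)
      }
    }
  }

  roots <- vapply(seq_len(m), find, integer(1))
  maf <- gm$snps$maf
  kept <- vapply(unique(roots), function(r) {
    members <- which(roots == r)
    members[which.max(maf[members])]  # which.max returns first (leftmost) tie
  }, integer(1))
  kept <- sort(kept)

  block_rows <- lapply(kept, function(r) {
    members <- which(roots == roots[r])
    data.frame(
      representative_id = gm$snps$snp_id[r],
      member_ids = paste(gm$snps$snp_id[members], collapse = ","),
      representative_index = r,
      n_members = length(members),
      stringsAsFactors = FALSE
    )
  })
  list(
    genotypes = subset_genotypes(gm, snps = kept),
    blocks = do.call(rbind, block_rows),
    kept = kept
  )
}

#' Write LD blocks as TSV
#'
#' @param blocks The `blocks` data.frame from [reduce_by_ld()].
#' @param path Output file.
#' @export
write_blocks_tsv <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
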