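# Shared fixture builders and independent oracles used across test files.

# quick genotype_matrix from a dosage matrix
make_gm <- function(dos, chrom = "1", pos = NULL, orient = TRUE) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  snps <- data.frame(
    snp_id = sprintf("snp%d", seq_len(m)),
    chrom = rep_len(chrom, m),
    pos = pos %||% (seq_len(m) * 10000L),
    allele_major = "A", allele_minor = "a",
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, snps, sample_ids = sprintf("s%d", seq_len(nrow(dos))),
                  orient = orient)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force SNP-to-gene assignment oracle (interval double loop)
brute_assign <- function(gm, genes) {
  out <- list()
  for (g in seq_len(nrow(genes))) {
    hits <- integer(0)
    for (j in seq_len(ncol(gm$dosages))) {
      if (gm$snps$chrom[j] == genes$chrom[g] &&
          gm$snps$pos[j] >= genes$region_start[g] &&
          gm$snps$pos[j] <= genes$region_end[g]) {
        hits <- c(hits, j)
      }
    }
    if (length(hits)) out[[genes$symbol[g]]] <- hits
  }
  out
}

# write a minimal VCF file; gts is a records x samples character matrix
# of GT strings, fix a data.frame with CHROM, POS, ID, REF, ALT
write_test_vcf <- function(path, fix, gts) {
  n_samp <- ncol(gts)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%d", seq_len(n_samp))), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(fix)), function(i) {
    paste(c(fix$CHROM[i], fix$POS[i], fix$ID[i], fix$REF[i], fix$ALT[i],
            ".", "PASS", ".", "GT", gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  path
}

# unordered SNP-pair key of target pairs for rank/false-positive checks
pair_keys <- function(pairs) {
  vapply(pairs, function(p) {
    paste(sort(sprintf("snp%d", p)), collapse = "|")
  }, "")
}

descriptor_pair_keys <- function(desc) {
  ifelse(desc$kind == "pair",
         paste(pmin(desc$snp1_id, desc$snp2_id),
               pmax(desc$snp1_id, desc$snp2_id), sep = "|"),
         "")
}

# rank (1 = best) of the best-ranked target-pair feature in a two-stage fit
target_best_rank <- function(fit, pairs, labels) {
  res <- fit$stage2$result
  if (is.null(res) || !length(res$frequencies)) return(NA_integer_)
  pv <- episelect:::chi2_pvalues(fit$stage2$features$values, labels)
  rk <- rank_features(res, pv)
  key <- descriptor_pair_keys(fit$stage2$features$descriptors)
  which(key[rk] %in% pair_keys(pairs))[1]
}

# number of selected pair features that are not target pairs
count_false_pairs <- function(fit, pairs) {
  res <- fit$stage2$result
  if (is.null(res) || !length(res$selected)) return(0L)
  d <- fit$stage2$features$descriptors[res$selected, , drop = FALSE]
  key <- descriptor_pair_keys(d)
  sum(d$kind == "pair" & !(key %in% pair_keys(pairs)))
}

# small, fast pipeline config for unit tests (not the study conditions)
fast_cfg <- function(seed = 1L, ...) {
  run_config(n_resamples = 50L, seed = seed, ...)
}
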