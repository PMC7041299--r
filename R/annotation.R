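# Gene annotation: interval tables, promoter extension, SNP-to-gene maps.
#
# Internal coordinates are 1-based inclusive (matching VCF/BIM positions);
# BED input (0-based half-open) is converted on read.

#' Load a gene interval table
#'
#' @param path Tab-separated file. For `ucsc_merged`, a pre-joined
#'   kgXref x knownGene style export with columns `geneSymbol`, `chrom`,
#'   `strand`, `txStart`, `txEnd` (header optional when columns are in this
#'   order), 1-based inclusive coordinates. For `bed`, BED6 whose `name`
#'   field is the gene symbol.
#' @param format One of `"ucsc_merged"` or `"bed"`.
#' @return A `data.frame` of class `gene_table` with one row per gene symbol:
#'   columns `symbol`, `chrom`, `strand`, `tx_start`, `tx_end`,
#'   `region_start`, `region_end`. Multiple transcripts of a symbol are
#'   collapsed to the leftmost start and rightmost end. `region_*` equals the
#'   transcript span until [extend_promoter()] is applied.
#' @export
load_gene_table <- function(path, format = c("ucsc_merged", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  if (format == "ucsc_merged") {
    first <- readLines(path, n = 1L)
    has_header <- grepl("geneSymbol|symbol", first)
    tab <- utils::read.delim(path, header = has_header,
                             stringsAsFactors = FALSE)
    if (!has_header) {
      names(tab)[1:5] <- c("geneSymbol", "chrom", "strand", "txStart", "txEnd")
    }
    tab <- data.frame(
      symbol = as.character(tab$geneSymbol), chrom = as.character(tab$chrom),
      strand = as.character(tab$strand),
      tx_start = as.integer(tab$txStart), tx_end = as.integer(tab$txEnd),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.table(path, stringsAsFactors = FALSE)
    if (ncol(tab) < 6L) stop("BED input needs 6 columns (through strand)",
                             call. = FALSE)
    tab <- data.frame(
      symbol = as.character(tab[[4L]]), chrom = as.character(tab[[1L]]),
      strand = as.character(tab[[6L]]),
      tx_start = as.integer(tab[[2L]]) + 1L,  # 0-based half-open -> 1-based
      tx_end = as.integer(tab[[3L]]),
      stringsAsFactors = FALSE
    )
  }
  if (any(is.na(tab$strand)) || !all(tab$strand %in% c("+", "-"))) {
    stop("gene table has missing/invalid strand values", call. = FALSE)
  }
  if (any(tab$tx_start > tab$tx_end)) {
    stop("gene table has start > end", call. = FALSE)
  }

  # collapse transcripts: leftmost start, rightmost end per symbol
  split_idx <- split(seq_len(nrow(tab)), tab$symbol)
  genes <- do.call(rbind, lapply(split_idx, function(i) {
    data.frame(
      symbol = tab$symbol[i[1L]], chrom = tab$chrom[i[1L]],
      strand = tab$strand[i[1L]],
      tx_start = min(tab$tx_start[i]), tx_end = max(tab$tx_end[i]),
      stringsAsFactors = FALSE
    )
  }))
  genes <- genes[order(genes$chrom, genes$tx_start), , drop = FALSE]
  rownames(genes) <- NULL
  genes$region_start <- genes$tx_start
  genes$region_end <- genes$tx_end
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Extend gene intervals by an upstream promoter region
#'
#' The promoter is taken strand-aware: `length` bp upstream of the
#' transcription start, i.e. before `tx_start` on the `+` strand and after
#' `tx_end` on the `-` strand. Coordinates are clamped at position 1.
#'
#' @param genes A `gene_table` from [load_gene_table()].
#' @param length Promoter length in bp (default 1000).
#' @return The `gene_table` with `region_start`/`region_end` updated.
#' @export
extend_promoter <- function(genes, length = 1000L) {
  if (length < 0L) stop("promoter length must be >= 0", call. = FALSE)
  plus <- genes$strand == "+"
  genes$region_start <- ifelse(plus, pmax(1L, genes$tx_start - as.integer(length)),
                               genes$tx_start)
  genes$region_end <- ifelse(plus, genes$tx_end,
                             genes$tx_end + as.integer(length))
  genes
}

#' Assign SNPs to gene regions
#'
#' A SNP belongs to every gene whose (promoter-extended) region contains its
#' position on the same chromosome; overlapping genes therefore share SNPs.
#' Genes without SNPs are omitted; SNPs outside all regions are simply not
#' listed (and drop out of downstream stages).
#'
#' @param gm A [genotype_matrix()].
#' @param genes A `gene_table` (after [extend_promoter()] if promoter
#'   inclusion is wanted).
#' @return A named list: gene symbol -> integer vector of SNP column indices
#'   into `gm`, in genomic order.
#' @export
assign_snps <- function(gm, genes) {
  out <- list()
  for (ch in unique(genes$chrom)) {
    g_idx <- which(genes$chrom == ch)
    s_idx <- which(gm$snps$chrom == ch)
    if (!length(s_idx)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(gm$snps$pos[s_idx], width = 1L),
      IRanges::IRanges(genes$region_start[g_idx], genes$region_end[g_idx])
    )
    if (!length(hits)) next
    q <- s_idx[S4Vectors::queryHits(hits)]
    s <- g_idx[S4Vectors::subjectHits(hits)]
    for (g in unique(s)) {
      out[[genes$symbol[g]]] <- sort(q[s == g])
    }
  }
  # keep gene-table order for determinism
  out[order(match(names(out), genes$symbol))]
}
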