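# Simulator of pure-epistasis case/control datasets with known ground truth.
#
# A target SNP pair carries a 3x3 penetrance table that is marginal-effect
# free: conditioned on either single locus, the expected penetrance equals
# the prevalence K, so all signal lives in the two-locus interaction.
# Heritability is defined on the binary-trait variance scale,
#   h2 = sum_g P(g) (pen(g) - K)^2 / (K (1 - K)),
# with P(g) the Hardy-Weinberg genotype probabilities of the pair.

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' Sample a pure-epistasis penetrance table
#'
#' Draws random 3x3 tables, projects them onto the marginal-effect-free
#' constraint set (weighted double-centering under Hardy-Weinberg genotype
#' probabilities), rescales the deviations around `K` to hit the target
#' heritability exactly, and retries until all penetrances fall in [0, 1].
#'
#' @param maf Minor allele frequency of both target SNPs, in (0, 0.5].
#' @param h2_target Target heritability in (0, 1).
#' @param K_target Disease prevalence (default 0.5, which makes balanced
#'   case/control sampling efficient).
#' @param seed Integer seed; the draw is deterministic per seed.
#' @param max_tries Retry budget before declaring infeasibility.
#' @return A list of class `penetrance_table`: `values` (3x3, rows indexed by
#'   SNP1 genotype AA/Aa/aa, columns by SNP2), `maf1`, `maf2`, `K`, `h2`.
#' @export
sample_penetrance <- function(maf, h2_target, K_target = 0.5, seed = 1L,
                              max_tries = 10000L) {
  stopifnot(maf > 0, maf <= 0.5, h2_target >= 0, h2_target < 1,
            K_target > 0, K_target < 1)
  if (h2_target == 0) {
    return(structure(
      list(values = matrix(K_target, 3L, 3L), maf1 = maf, maf2 = maf,
           K = K_target, h2 = 0),
      class = "penetrance_table"
    ))
  }
  p <- hwe_probs(maf)
  q <- hwe_probs(maf)
  w <- outer(p, q)
  target_var <- h2_target * K_target * (1 - K_target)

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      d0 <- matrix(stats::runif(9L, -1, 1), 3L, 3L)
      # weighted two-way interaction component: row/column weighted means -> 0
      r <- as.numeric(d0 %*% q)
      cc <- as.numeric(crossprod(d0, p))
      g <- as.numeric(p %*% d0 %*% q)
      d <- d0 - outer(r, rep(1, 3L)) - outer(rep(1, 3L), cc) + g
      v <- sum(w * d^2)
      if (v < 1e-12) next
      f <- K_target + sqrt(target_var / v) * d
      if (all(f >= 0 & f <= 1)) {
        return(structure(
          list(values = f, maf1 = maf, maf2 = maf, K = K_target,
               h2 = h2_target),
          class = "penetrance_table"
        ))
      }
    }
  })
  stop(sprintf(
    paste0("no feasible pure-epistasis table after %d draws: h2 = %.3g is ",
           "too large for maf = %.3g, K = %.3g (rare-genotype penetrances ",
           "leave [0, 1])"),
    max_tries, h2_target, maf, K_target
  ), call. = FALSE)
}

#' Validate penetrance-table invariants
#'
#' Recomputes prevalence, heritability and the marginal penetrances from the
#' table and its Hardy-Weinberg weights.
#'
#' @param pt A `penetrance_table`.
#' @param tol Tolerance for the equality checks.
#' @return Invisibly `TRUE`; errors describing the first violated invariant
#'   otherwise.
#' @export
check_penetrance <- function(pt, tol = 1e-6) {
  p <- hwe_probs(pt$maf1)
  q <- hwe_probs(pt$maf2)
  w <- outer(p, q)
  K <- sum(w * pt$values)
  if (abs(K - pt$K) > tol) stop("prevalence mismatch", call. = FALSE)
  h2 <- sum(w * (pt$values - K)^2) / (K * (1 - K))
  if (abs(h2 - pt$h2) > tol) stop("heritability mismatch", call. = FALSE)
  if (max(abs(as.numeric(pt$values %*% q) - K)) > tol) {
    stop("SNP1 marginal penetrance not flat", call. = FALSE)
  }
  if (max(abs(as.numeric(crossprod(pt$values, p)) - K)) > tol) {
    stop("SNP2 marginal penetrance not flat", call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions of the published simulation design:
#' 2000 individuals, case/control ratio 1, 100 SNPs, target-pair MAF 0.2 and
#' heritability 0.2, 100 replicates.
#'
#' @param n_individuals Samples per replicate.
#' @param case_control_ratio Cases per control.
#' @param n_snps Total SNPs (targets + noise).
#' @param n_replicates Replicates the configuration describes.
#' @param n_target_pairs Number of embedded epistatic pairs (1 = basic model,
#'   3 = combined/complex model). Ignored when `target_tables` is supplied.
#' @param target_maf,target_h2,prevalence Penetrance-table parameters used to
#'   sample one table per pair (distinct seeded draws stand in for distinct
#'   models at identical MAF/h2).
#' @param target_tables Optional list of `penetrance_table` objects to embed
#'   as-is.
#' @param noise_maf_range MAF bounds for the independent noise SNPs.
#' @param seed Master seed; per-replicate seeds derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000L, case_control_ratio = 1,
                       n_snps = 100L, n_replicates = 100L,
                       n_target_pairs = 1L, target_maf = 0.2,
                       target_h2 = 0.2, prevalence = 0.5,
                       target_tables = NULL,
                       noise_maf_range = c(0.05, 0.5), seed = 1L) {
  if (is.null(target_tables)) {
    target_tables <- lapply(seq_len(n_target_pairs), function(m) {
      sample_penetrance(target_maf, target_h2, prevalence,
                        seed = derive_seed(seed, 700L + m))
    })
  }
  if (2L * length(target_tables) > n_snps) {
    stop("more target SNPs than n_snps", call. = FALSE)
  }
  stopifnot(case_control_ratio > 0, n_individuals >= 4L,
            noise_maf_range[1] > 0, noise_maf_range[2] <= 0.5)
  structure(
    list(n_individuals = as.integer(n_individuals),
         case_control_ratio = case_control_ratio,
         n_snps = as.integer(n_snps),
         n_replicates = as.integer(n_replicates),
         target_tables = target_tables,
         noise_maf_range = noise_maf_range, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate one replicate dataset
#'
#' Target-pair genotypes are drawn from Hardy-Weinberg proportions at the
#' table's MAF; disease status is Bernoulli in the table's penetrance. With
#' several target pairs each individual's status is governed by one pair
#' (assigned uniformly at random), emulating the heterogeneous combination of
#' several basic models into one dataset. Sampling continues (by class
#' rejection) until the configured case and control counts are reached.
#' Noise SNPs are Hardy-Weinberg with MAF uniform in `noise_maf_range`,
#' independent of status. Target pairs occupy adjacent, randomly placed,
#' recorded columns.
#'
#' @param cfg A [sim_config()].
#' @param replicate Replicate number (>= 1); the replicate seed is derived
#'   from `cfg$seed` and this index.
#' @return A list: `genotypes` ([genotype_matrix()]), `phenotype`
#'   ([phenotype()]), `truth` (list with `pairs` - a list of length-2 column
#'   index vectors - plus `tables` and `seed`).
#' @export
simulate_dataset <- function(cfg, replicate = 1L) {
  seed_r <- derive_seed(cfg$seed, replicate)
  n <- cfg$n_individuals
  r <- cfg$case_control_ratio
  n_cases <- as.integer(round(n * r / (1 + r)))
  n_ctrl <- n - n_cases
  if (n_cases < 1L || n_ctrl < 1L) stop("degenerate case/control split",
                                        call. = FALSE)
  n_pairs <- length(cfg$target_tables)

  if (n_pairs == 0L) {
    # pure-noise dataset: balanced random labels, every SNP independent
    return(with_seed(seed_r, {
      y <- sample(c(rep(1L, n_cases), rep(-1L, n_ctrl)))
      dos <- matrix(NA_integer_, n, cfg$n_snps)
      maf <- stats::runif(cfg$n_snps, cfg$noise_maf_range[1],
                          cfg$noise_maf_range[2])
      for (j in seq_len(cfg$n_snps)) dos[, j] <- stats::rbinom(n, 2L, maf[j])
      snps <- data.frame(
        snp_id = sprintf("snp%d", seq_len(cfg$n_snps)), chrom = "1",
        pos = seq_len(cfg$n_snps) * 10000L,
        allele_major = "A", allele_minor = "a", stringsAsFactors = FALSE
      )
      list(
        genotypes = genotype_matrix(dos, snps,
                                    sample_ids = sprintf("ind%04d",
                                                         seq_len(n))),
        phenotype = phenotype(y),
        truth = list(pairs = list(), tables = list(), seed = seed_r)
      )
    }))
  }

  with_seed(seed_r, {
    # adjacent non-overlapping column pairs for the targets
    starts <- integer(0)
    avail <- seq_len(cfg$n_snps - 1L)
    for (m in seq_len(n_pairs)) {
      ok <- avail[!(avail %in% c(starts, starts - 1L, starts + 1L))]
      if (!length(ok)) stop("n_snps too small to place target pairs",
                            call. = FALSE)
      starts <- c(starts, if (length(ok) == 1L) ok else sample(ok, 1L))
    }
    pairs <- lapply(starts, function(s) c(s, s + 1L))

    # class-rejection sampling of target genotypes + status
    kept_geno <- matrix(NA_integer_, 0L, 2L * n_pairs)
    kept_y <- integer(0)
    need <- c(cases = n_cases, controls = n_ctrl)
    tries <- 0L
    while (need["cases"] > 0L || need["controls"] > 0L) {
      tries <- tries + 1L
      if (tries > 200L) {
        stop("class quotas unreachable (prevalence too extreme)", call. = FALSE)
      }
      b <- max(2L * n, 1000L)
      geno <- matrix(NA_integer_, b, 2L * n_pairs)
      for (m in seq_len(n_pairs)) {
        maf <- cfg$target_tables[[m]]$maf1
        geno[, 2L * m - 1L] <- stats::rbinom(b, 2L, maf)
        geno[, 2L * m] <- stats::rbinom(b, 2L, cfg$target_tables[[m]]$maf2)
      }
      model <- sample.int(n_pairs, b, replace = TRUE)
      pen <- vapply(seq_len(b), function(i) {
        m <- model[i]
        cfg$target_tables[[m]]$values[geno[i, 2L * m - 1L] + 1L,
                                      geno[i, 2L * m] + 1L]
      }, numeric(1))
      y <- ifelse(stats::rbinom(b, 1L, pen) == 1L, 1L, -1L)

      take_case <- which(y == 1L)[seq_len(min(need["cases"], sum(y == 1L)))]
      take_ctrl <- which(y == -1L)[seq_len(min(need["controls"],
                                               sum(y == -1L)))]
      take <- c(take_case, take_ctrl)
      kept_geno <- rbind(kept_geno, geno[take, , drop = FALSE])
      kept_y <- c(kept_y, y[take])
      need["cases"] <- n_cases - sum(kept_y == 1L)
      need["controls"] <- n_ctrl - sum(kept_y == -1L)
    }
    ord <- sample.int(n)  # shuffle so classes are interleaved
    kept_geno <- kept_geno[ord, , drop = FALSE]
    kept_y <- kept_y[ord]

    dos <- matrix(NA_integer_, n, cfg$n_snps)
    target_cols <- unlist(pairs)
    for (m in seq_len(n_pairs)) {
      dos[, pairs[[m]][1L]] <- kept_geno[, 2L * m - 1L]
      dos[, pairs[[m]][2L]] <- kept_geno[, 2L * m]
    }
    noise_cols <- setdiff(seq_len(cfg$n_snps), target_cols)
    noise_maf <- stats::runif(length(noise_cols), cfg$noise_maf_range[1],
                              cfg$noise_maf_range[2])
    for (jj in seq_along(noise_cols)) {
      dos[, noise_cols[jj]] <- stats::rbinom(n, 2L, noise_maf[jj])
    }

    snps <- data.frame(
      snp_id = sprintf("snp%d", seq_len(cfg$n_snps)),
      chrom = "1",
      pos = seq_len(cfg$n_snps) * 10000L,
      allele_major = "A", allele_minor = "a",
      stringsAsFactors = FALSE
    )
    gm <- genotype_matrix(dos, snps,
                          sample_ids = sprintf("ind%04d", seq_len(n)))
    list(
      genotypes = gm,
      phenotype = phenotype(kept_y),
      truth = list(pairs = pairs, tables = cfg$target_tables, seed = seed_r)
    )
  })
}

#' Synthetic gene table for simulated SNPs
#'
#' Bins consecutive SNP columns into synthetic genes so the two-stage
#' pipeline can run on simulated data (which has no genes of its own). In
#' `"within"` mode bin boundaries falling between the two SNPs of a target
#' pair are removed, so each pair shares a gene; in `"across"` mode a
#' boundary is inserted between them, so each pair spans two genes.
#'
#' @param n_snps Number of SNP columns.
#' @param target_pairs List of length-2 column index vectors (from
#'   `simulate_dataset()$truth$pairs`).
#' @param snps_per_gene Baseline bin width (default 10).
#' @param mode `"within"` or `"across"`.
#' @param spacing Basepair spacing of simulated SNP positions (matches
#'   [simulate_dataset()]).
#' @return A `gene_table` (see [load_gene_table()]) whose regions cover the
#'   binned SNP positions; consumable by [assign_snps()] and writable with
#'   [write_gene_table()].
#' @export
assign_simulated_genes <- function(n_snps, target_pairs = list(),
                                   snps_per_gene = 10L,
                                   mode = c("within", "across"),
                                   spacing = 10000L) {
  mode <- match.arg(mode)
  stopifnot(snps_per_gene >= 1L)
  cuts <- if (snps_per_gene < n_snps) {
    seq(snps_per_gene, n_snps - 1L, by = snps_per_gene)  # cut after column
  } else {
    integer(0)
  }
  for (pr in target_pairs) {
    lo <- min(pr)
    hi <- max(pr)
    between <- cuts[cuts >= lo & cuts < hi]
    if (mode == "within") {
      cuts <- setdiff(cuts, between)
    } else if (!length(between)) {
      cuts <- sort(c(cuts, lo))
    }
  }
  bounds <- c(0L, sort(unique(cuts)), n_snps)
  genes <- data.frame(
    symbol = sprintf("GENE%02d", seq_len(length(bounds) - 1L)),
    chrom = "1", strand = "+",
    tx_start = (utils::head(bounds, -1L) + 1L) * spacing,
    tx_end = bounds[-1L] * spacing,
    stringsAsFactors = FALSE
  )
  genes$region_start <- genes$tx_start
  genes$region_end <- genes$tx_end
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Write a gene table in the UCSC-style merged format
#'
#' @param genes A `gene_table`.
#' @param path Output TSV (columns geneSymbol, chrom, strand, txStart, txEnd).
#' @export
write_gene_table <- function(genes, path) {
  tab <- data.frame(geneSymbol = genes$symbol, chrom = genes$chrom,
                    strand = genes$strand, txStart = genes$tx_start,
                    txEnd = genes$tx_end)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
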