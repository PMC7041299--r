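# End-to-end entry points: discovery on genotype files and batch simulation.

#' Run the full discovery pipeline on input files
#'
#' Reads genotypes (VCF or PLINK prefix), phenotype and gene table, applies
#' LD reduction and gene assignment (label-free, on all samples), runs the
#' two-stage discovery, evaluates by double CV, and writes the report
#' (TSV + JSON), CV table, LD blocks and the configuration used into
#' `out_dir`.
#'
#' @param genotypes Path to a VCF file or a PLINK fileset prefix.
#' @param genes Path to the gene table.
#' @param out_dir Output directory (created if needed).
#' @param phenotype_csv Optional phenotype CSV (`sample_id,label`); when
#'   `NULL` the PLINK .fam/.ped phenotype column is used.
#' @param covariates_csv Optional covariate CSV (first column `sample_id`).
#' @param gene_format Passed to [load_gene_table()].
#' @param cfg A [run_config()].
#' @param cv_modes Character subset of `c("training", "2fold", "loo")`.
#' @return Invisibly, a list: `fit` (`two_stage_fit`), `cv` (list of
#'   `cv_report`), `blocks`, `out_dir`.
#' @export
run_discover <- function(genotypes, genes, out_dir,
                         phenotype_csv = NULL, covariates_csv = NULL,
                         gene_format = "ucsc_merged", cfg = run_config(),
                         cv_modes = c("training", "2fold")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (grepl("\\.vcf(\\.gz)?$", genotypes)) {
    gm <- read_vcf(genotypes)
    phen <- NULL
  } else {
    loaded <- read_plink(genotypes)
    gm <- loaded$genotypes
    phen <- loaded$phenotype
  }
  if (!is.null(phenotype_csv)) {
    phen <- read_phenotype_csv(phenotype_csv, sample_ids = gm$sample_ids)
  }
  if (is.null(phen)) {
    stop("no phenotype: supply phenotype_csv or a PLINK phenotype column",
         call. = FALSE)
  }
  covar <- NULL
  if (!is.null(covariates_csv)) {
    ct <- utils::read.csv(covariates_csv, stringsAsFactors = FALSE)
    m <- match(gm$sample_ids, ct[[1L]])
    if (anyNA(m)) stop("covariate file is missing samples", call. = FALSE)
    covar <- as.matrix(ct[m, -1L, drop = FALSE])
  }

  gene_tab <- extend_promoter(load_gene_table(genes, gene_format),
                              cfg$promoter_length)
  message(sprintf("loaded %d samples x %d SNPs, %d genes",
                  nrow(gm$dosages), ncol(gm$dosages), nrow(gene_tab)))

  red <- reduce_by_ld(gm, cfg$dprime_thresh, cfg$r2_thresh, cfg$ld_window)
  message(sprintf("LD reduction: %d -> %d SNPs", ncol(gm$dosages),
                  ncol(red$genotypes$dosages)))
  gene_map <- assign_snps(red$genotypes, gene_tab)
  message(sprintf("%d genes carry SNPs (%d SNP-gene assignments)",
                  length(gene_map), sum(lengths(gene_map))))

  fit <- run_two_stage(red$genotypes, phen, gene_map, cfg,
                       covariates = covar, verbose = TRUE)

  cv <- list()
  if ("training" %in% cv_modes) {
    cv$training <- training_report(fit, red$genotypes, phen)
  }
  if ("2fold" %in% cv_modes) {
    cv$external_2fold <- double_cv(red$genotypes, phen, gene_map, cfg,
                                   external = "2fold")
  }
  if ("loo" %in% cv_modes) {
    cv$external_loo <- double_cv(red$genotypes, phen, gene_map, cfg,
                                 external = "loo")
  }

  write_report(fit, red, cv, cfg, out_dir)
  invisible(list(fit = fit, cv = cv, blocks = red$blocks, out_dir = out_dir))
}

write_report <- function(fit, red, cv, cfg, out_dir) {
  rep_tab <- fit$report$features
  utils::write.table(rep_tab, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_blocks_tsv(red$blocks, file.path(out_dir, "blocks.tsv"))
  if (length(cv)) write_cv_tsv(cv, file.path(out_dir, "cv.tsv"))

  block_members <- stats::setNames(
    strsplit(red$blocks$member_ids, ","), red$blocks$representative_id
  )
  payload <- list(
    features = rep_tab,
    intercept = fit$report$intercept,
    ld_blocks = block_members,
    cv = lapply(cv, function(r) r[c("mode", "precision", "recall", "f1",
                                    "accuracy")]),
    config = unclass(cfg)
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Generate a batch of simulated replicate datasets on disk
#'
#' Each replicate directory receives a PLINK triple, a ground-truth JSON
#' (target columns, penetrance tables, replicate seed) and synthetic gene
#' tables for both placement modes.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param snps_per_gene Bin width for the synthetic gene tables.
#' @return Invisibly, the replicate directories.
#' @export
run_simulate <- function(cfg, out_dir, snps_per_gene = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- character(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    d <- file.path(out_dir, sprintf("replicate%03d", r))
    dir.create(d, showWarnings = FALSE)
    sim <- simulate_dataset(cfg, r)
    write_plink(sim$genotypes, sim$phenotype, file.path(d, "genotypes"))
    for (mode in c("within", "across")) {
      write_gene_table(
        assign_simulated_genes(cfg$n_snps, sim$truth$pairs, snps_per_gene,
                               mode),
        file.path(d, sprintf("genes_%s.tsv", mode))
      )
    }
    truth <- list(
      pairs = sim$truth$pairs,
      tables = lapply(sim$truth$tables, function(t) {
        list(values = t$values, maf1 = t$maf1, maf2 = t$maf2, K = t$K,
             h2 = t$h2)
      }),
      seed = sim$truth$seed
    )
    jsonlite::write_json(truth, file.path(d, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dirs[r] <- d
  }
  jsonlite::write_json(
    unclass(cfg)[setdiff(names(unclass(cfg)), "target_tables")],
    file.path(out_dir, "sim_config.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dirs)
}
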