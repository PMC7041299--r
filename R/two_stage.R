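# Two-stage epistasis discovery: stage 1 models each gene independently on
# its combinatorially encoded features; stage 2 pools the stage-1 selections
# from genes with non-zero F1, crosses their single-SNP features across genes
# into candidate cross-gene interaction blocks, and models the merged design
# once more with stability selection.

#' Pipeline configuration
#'
#' Collects the thresholds and stability-selection settings of the two-stage
#' workflow. Defaults follow the published method: genotype frequency > 5%,
#' stage-1 chi-squared p < 0.01, stage-2 (cross-gene candidate) p < 1e-5,
#' LD thresholds D' > 0.9 and r^2 > 0.9, 500 stability-selection rounds.
#'
#' @param freq_min Genotype-frequency threshold (strict).
#' @param p_stage1 Stage-1 chi-squared threshold (strict).
#' @param p_stage2 Stage-2 threshold applied to new cross-gene candidates
#'   (strict). Set `stage2_filter_carryover = TRUE` to also re-filter the
#'   carried-over stage-1 features at this threshold.
#' @param dprime_thresh,r2_thresh,ld_window LD reduction parameters, see
#'   [reduce_by_ld()].
#' @param promoter_length Upstream promoter extension in bp.
#' @param n_resamples,subsample_fraction,selection_threshold,n_lambda,lambda_min_ratio,selection_min_ratio,per_round_cap,method
#'   Stability-selection settings, see [l1_config()].
#' @param stage2_filter_carryover Logical, see `p_stage2`.
#' @param seed Integer run seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(freq_min = 0.05, p_stage1 = 0.01, p_stage2 = 1e-5,
                       dprime_thresh = 0.9, r2_thresh = 0.9,
                       ld_window = 1000L, promoter_length = 1000L,
                       n_resamples = 500L, subsample_fraction = 0.5,
                       selection_threshold = 0.6, n_lambda = 10L,
                       lambda_min_ratio = 1e-3, selection_min_ratio = 0.1,
                       per_round_cap = NULL,
                       method = c("stability", "plain"),
                       stage2_filter_carryover = FALSE, seed = 1L) {
  stopifnot(freq_min >= 0, freq_min < 1, p_stage1 > 0, p_stage1 <= 1,
            p_stage2 > 0, p_stage2 <= 1,
            dprime_thresh >= 0, dprime_thresh <= 1,
            r2_thresh >= 0, r2_thresh <= 1, promoter_length >= 0)
  structure(
    list(freq_min = freq_min, p_stage1 = p_stage1, p_stage2 = p_stage2,
         dprime_thresh = dprime_thresh, r2_thresh = r2_thresh,
         ld_window = as.integer(ld_window),
         promoter_length = as.integer(promoter_length),
         n_resamples = as.integer(n_resamples),
         subsample_fraction = subsample_fraction,
         selection_threshold = selection_threshold,
         n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio,
         selection_min_ratio = selection_min_ratio,
         per_round_cap = if (!is.null(per_round_cap)) as.integer(per_round_cap),
         method = match.arg(method),
         stage2_filter_carryover = stage2_filter_carryover,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

cfg_l1 <- function(cfg, seed) {
  l1_config(n_resamples = cfg$n_resamples,
            subsample_fraction = cfg$subsample_fraction,
            selection_threshold = cfg$selection_threshold,
            n_lambda = cfg$n_lambda, lambda_min_ratio = cfg$lambda_min_ratio,
            selection_min_ratio = cfg$selection_min_ratio,
            per_round_cap = cfg$per_round_cap,
            method = cfg$method, seed = seed)
}

empty_gene_result <- function(gene) {
  structure(
    list(gene = gene, selected_descriptors = NULL, result = NULL,
         gene_f1 = 0),
    class = "gene_stage_result"
  )
}

#' Stage 1: within-gene feature selection for one gene
#'
#' Builds the gene's combinatorial design, applies the
#' (frequency, chi-squared) quality filter, runs stability selection, and
#' scores the refit gene model by stratified 2-fold CV F1. Genes whose
#' features all fail the filter yield an empty selection with `gene_f1 = 0`.
#'
#' @param gm A [genotype_matrix()].
#' @param phen A [phenotype()].
#' @param gene Gene symbol (for labelling).
#' @param snp_indices Columns of `gm` assigned to the gene.
#' @param cfg A [run_config()].
#' @param seed Seed for this gene (derived from the run seed by the caller).
#' @return A list of class `gene_stage_result`: `gene`,
#'   `selected_descriptors` (with `freq`, `chi2_p`, `frequency` columns),
#'   `result` (the `stability_result`), `gene_f1`.
#' @export
stage1_gene <- function(gm, phen, gene, snp_indices, cfg = run_config(),
                        seed = cfg$seed) {
  fm <- gene_feature_matrix(gm, snp_indices, gene_label = gene)
  fm <- filter_features(fm, phen, cfg$freq_min, cfg$p_stage1)
  if (ncol(fm$values) == 0L) return(empty_gene_result(gene))

  res <- stability_select(fm$values, phen$labels, cfg_l1(cfg, seed),
                          descriptors = fm$descriptors)
  if (!length(res$selected)) return(empty_gene_result(gene))

  sel_desc <- fm$descriptors[res$selected, , drop = FALSE]
  sel_desc$frequency <- res$frequencies[res$selected]
  sel_desc$coefficient <- unname(res$coefficients)

  gene_f1 <- cv2_f1(fm$values[, res$selected, drop = FALSE], phen$labels,
                    res$lambda_grid, derive_seed(seed, 11L))
  structure(
    list(gene = gene, selected_descriptors = sel_desc, result = res,
         gene_f1 = gene_f1),
    class = "gene_stage_result"
  )
}

# Stratified 2-fold CV F1 of an L1 refit on the given (selected) columns.
cv2_f1 <- function(X, y, lambda_grid, seed) {
  foldid <- with_seed(seed, stratified_folds(y, 2L))
  pred <- integer(length(y))
  for (f in 1:2) {
    tr <- which(foldid != f)
    te <- which(foldid == f)
    fit <- refit_cv(X[tr, , drop = FALSE], y[tr], lambda_grid,
                    derive_seed(seed, f))
    eta <- X[te, , drop = FALSE] %*% fit$weights + fit$intercept
    pred[te] <- ifelse(as.numeric(eta) > 0, 1L, -1L)
  }
  metrics(y, pred)["f1"][[1L]]
}

# Deduplicate pooled descriptors by display label, merging gene labels.
pool_descriptors <- function(desc_list) {
  pool <- do.call(rbind, desc_list)
  if (is.null(pool) || !nrow(pool)) return(NULL)
  keep <- !duplicated(pool$label)
  merged <- pool[keep, , drop = FALSE]
  for (i in which(duplicated(pool$label))) {
    j <- match(pool$label[i], merged$label)
    g <- union(strsplit(merged$genes1[j], ",")[[1L]],
               strsplit(pool$genes1[i], ",")[[1L]])
    merged$genes1[j] <- paste(sort(g), collapse = ",")
  }
  rownames(merged) <- NULL
  merged
}

gene_set <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]

#' Stage 2: cross-gene epistasis discovery
#'
#' Pools all stage-1 selections from genes with non-zero F1 (single-SNP and
#' within-gene pair features), generates one nine-term candidate interaction
#' block for every unordered pair of pooled single-SNP features whose gene
#' sets are disjoint, filters the candidates at
#' (frequency > `freq_min`, chi-squared p < `p_stage2`), and runs stability
#' selection on the merged design.
#'
#' @param stage1_results List of `gene_stage_result` objects.
#' @param gm A [genotype_matrix()].
#' @param phen A [phenotype()].
#' @param cfg A [run_config()].
#' @return A list of class `stage2_result`: `result` (`stability_result`),
#'   `features` (the merged `feature_matrix`), `n_carryover`,
#'   `n_candidates_prefilter`, `n_candidates` and `status` (`"ok"` or
#'   `"no_admitted_genes"`).
#' @export
stage2_cross <- function(stage1_results, gm, phen, cfg = run_config()) {
  admitted <- Filter(function(r) r$gene_f1 > 0 &&
                       !is.null(r$selected_descriptors), stage1_results)
  if (!length(admitted)) {
    return(structure(
      list(result = NULL, features = NULL, n_carryover = 0L,
           n_candidates_prefilter = 0L, n_candidates = 0L,
           status = "no_admitted_genes"),
      class = "stage2_result"
    ))
  }
  pool <- pool_descriptors(lapply(admitted, `[[`, "selected_descriptors"))
  carry <- features_from_descriptors(gm, pool)
  if (isTRUE(cfg$stage2_filter_carryover)) {
    carry <- filter_features(carry, phen, cfg$freq_min, cfg$p_stage2)
  }

  # cross-gene candidates from pooled single-SNP features
  singles <- pool[pool$kind == "single", , drop = FALSE]
  snp_tab <- unique(data.frame(snp_id = singles$snp1_id,
                               genes = singles$genes1,
                               stringsAsFactors = FALSE))
  cand_values <- list()
  cand_desc <- list()
  n_pairs <- 0L
  if (nrow(snp_tab) >= 2L) {
    for (i in seq_len(nrow(snp_tab) - 1L)) {
      for (j in seq(i + 1L, nrow(snp_tab))) {
        if (snp_tab$snp_id[i] == snp_tab$snp_id[j]) next
        if (length(intersect(gene_set(snp_tab$genes[i]),
                             gene_set(snp_tab$genes[j])))) next
        n_pairs <- n_pairs + 1L
        c1 <- one_hot(gm, match(snp_tab$snp_id[i], gm$snps$snp_id))
        c2 <- one_hot(gm, match(snp_tab$snp_id[j], gm$snps$snp_id))
        cand_values[[n_pairs]] <- interaction_block(c1, c2)
        cand_desc[[n_pairs]] <- pair_descriptors(
          snp_tab$snp_id[i], snp_tab$genes[i],
          snp_tab$snp_id[j], snp_tab$genes[j], cross_gene = TRUE
        )
      }
    }
  }
  n_prefilter <- 9L * n_pairs
  if (n_pairs > 0L) {
    cand <- new_feature_matrix(do.call(cbind, cand_values),
                               do.call(rbind, cand_desc))
    cand <- filter_features(cand, phen, cfg$freq_min, cfg$p_stage2)
  } else {
    cand <- NULL
  }

  desc <- carry$descriptors
  values <- carry$values
  if (!is.null(cand) && ncol(cand$values)) {
    new_cols <- !(cand$descriptors$label %in% desc$label)
    values <- cbind(values, cand$values[, new_cols, drop = FALSE])
    desc <- merge_descriptor_rows(desc, cand$descriptors[new_cols, ,
                                                         drop = FALSE])
  }
  fm <- new_feature_matrix(values, desc)
  res <- stability_select(fm$values, phen$labels,
                          cfg_l1(cfg, derive_seed(cfg$seed, 999L)),
                          descriptors = fm$descriptors)
  structure(
    list(result = res, features = fm, n_carryover = ncol(carry$values),
         n_candidates_prefilter = n_prefilter,
         n_candidates = if (is.null(cand)) 0L else ncol(cand$values),
         status = "ok"),
    class = "stage2_result"
  )
}

# rbind descriptor frames that may differ in bookkeeping columns
merge_descriptor_rows <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cn in setdiff(cols, names(a))) a[[cn]] <- NA
  for (cn in setdiff(cols, names(b))) b[[cn]] <- NA
  rbind(a[cols], b[cols])
}

#' Final model report
#'
#' For every feature selected at stage 2: refit weight, odds ratio from the
#' feature-by-phenotype 2x2 table (Haldane 0.5 correction on zero cells),
#' chi-squared p-value, genotype frequency and gene labels (cross-gene
#' features join their gene sets with `*`). Optional covariates are appended
#' to the final refit unpenalized and reported alongside. Rows are sorted by
#' chi-squared p. The sign of each weight is checked against its odds ratio
#' (causal: weight > 0 and OR > 1; protective: the reverse); disagreements,
#' which can arise from conditioning in the multivariate refit, are flagged
#' in `sign_consistent` with a warning.
#'
#' @param stage2 A `stage2_result`.
#' @param phen A [phenotype()].
#' @param covariates Optional numeric `data.frame`/matrix of per-sample
#'   covariates (unpenalized in the refit, never stability-selected).
#' @param cfg A [run_config()].
#' @return A list of class `epi_report`: `features` (data.frame), `intercept`,
#'   `covariate_weights`.
#' @export
build_report <- function(stage2, phen, covariates = NULL,
                         cfg = run_config()) {
  if (is.null(stage2$result) || !length(stage2$result$selected)) {
    return(structure(
      list(features = data.frame(), intercept = NA_real_,
           covariate_weights = NULL, status = stage2$status),
      class = "epi_report"
    ))
  }
  res <- stage2$result
  sel <- res$selected
  X <- stage2$features$values[, sel, drop = FALSE]
  desc <- stage2$features$descriptors[sel, , drop = FALSE]
  weights <- unname(res$coefficients)
  intercept <- res$intercept
  cov_w <- NULL

  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    Xc <- cbind(X, C)
    pf <- c(rep(1, ncol(X)), rep(0, ncol(C)))
    lam_g <- sort(unique(res$lambda_grid / nrow(Xc)), decreasing = TRUE)
    fit <- glmnet::glmnet(Xc, factor(phen$labels, levels = c(-1, 1)),
                          family = "binomial", lambda = lam_g,
                          penalty.factor = pf, standardize = FALSE)
    s <- if (is.na(res$refit_lambda)) lam_g[length(lam_g)] else
      res$refit_lambda / nrow(Xc)
    k <- which.min(abs(fit$lambda - s))
    beta <- as.numeric(fit$beta[, k])
    weights <- beta[seq_len(ncol(X))]
    cov_w <- stats::setNames(beta[-seq_len(ncol(X))], colnames(C))
    intercept <- fit$a0[[k]]
  }

  y <- phen$labels
  pos <- y == 1L
  a <- colSums(X[pos, , drop = FALSE])
  b <- sum(pos) - a
  c1 <- colSums(X) - a
  d <- sum(!pos) - c1
  zero <- a == 0 | b == 0 | c1 == 0 | d == 0
  or <- ifelse(zero,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c1 + 0.5)),
               (a * d) / (b * c1))
  p <- chi2_pvalues(X, y)
  freq <- colMeans(X)
  genes <- ifelse(desc$cross_gene,
                  paste(desc$genes1, desc$genes2, sep = "*"),
                  desc$genes1)

  tab <- data.frame(
    feature = desc$label, weight = weights, odds_ratio = or,
    chi2_p = p, genotype_frequency = freq, gene = genes,
    cross_gene = desc$cross_gene,
    selection_frequency = res$frequencies[sel],
    sign_consistent = (weights >= 0) == (or >= 1) | weights == 0,
    stringsAsFactors = FALSE
  )
  if (!all(tab$sign_consistent)) {
    warning("weight sign and odds ratio disagree for ",
            sum(!tab$sign_consistent), " feature(s)")
  }
  tab <- tab[order(tab$chi2_p), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(features = tab, intercept = intercept, covariate_weights = cov_w,
         status = "ok"),
    class = "epi_report"
  )
}

#' @export
print.epi_report <- function(x, ...) {
  if (!nrow(x$features)) {
    cat("epi_report: empty model (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("epi_report: %d features (%d cross-gene), intercept %.3f\n",
              nrow(x$features), sum(x$features$cross_gene), x$intercept))
  print(x$features[, c("feature", "weight", "odds_ratio", "chi2_p",
                       "genotype_frequency", "gene")], digits = 3)
  invisible(x)
}

#' Run the full two-stage discovery on prepared inputs
#'
#' Takes an (LD-reduced) genotype matrix, phenotype and gene-to-SNP map, runs
#' stage 1 per gene and stage 2 across genes, and assembles the report.
#'
#' @param gm A [genotype_matrix()].
#' @param phen A [phenotype()].
#' @param gene_map Named list from [assign_snps()].
#' @param cfg A [run_config()].
#' @param covariates Optional covariate table for [build_report()].
#' @param verbose Print the per-stage feature-count funnel.
#' @return A list of class `two_stage_fit`: `stage1` (list of
#'   `gene_stage_result`), `stage2`, `report`, `cfg`.
#' @export
run_two_stage <- function(gm, phen, gene_map, cfg = run_config(),
                          covariates = NULL, verbose = FALSE) {
  stage1 <- vector("list", length(gene_map))
  names(stage1) <- names(gene_map)
  for (g in seq_along(gene_map)) {
    stage1[[g]] <- stage1_gene(gm, phen, names(gene_map)[g], gene_map[[g]],
                               cfg, seed = derive_seed(cfg$seed, g))
  }
  n_sel <- sum(vapply(stage1, function(r) {
    if (is.null(r$selected_descriptors)) 0L else nrow(r$selected_descriptors)
  }, integer(1)))
  if (verbose) {
    message(sprintf("stage 1: %d genes, %d features selected, %d genes admitted",
                    length(stage1), n_sel,
                    sum(vapply(stage1, function(r) r$gene_f1 > 0, logical(1)))))
  }
  stage2 <- stage2_cross(stage1, gm, phen, cfg)
  if (verbose && stage2$status == "ok") {
    message(sprintf(
      "stage 2: %d carried features + %d/%d cross-gene candidates -> %d selected",
      stage2$n_carryover, stage2$n_candidates, stage2$n_candidates_prefilter,
      length(stage2$result$selected)
    ))
  }
  report <- build_report(stage2, phen, covariates, cfg)
  structure(list(stage1 = stage1, stage2 = stage2, report = report,
                 cfg = cfg),
            class = "two_stage_fit")
}

# Predict {-1,+1} for samples of `gm` from a fitted two-stage model.
# Empty models predict the training majority class (passed as fallback).
predict_two_stage <- function(fit, gm, fallback = 1L) {
  s2 <- fit$stage2
  if (is.null(s2$result) || !length(s2$result$selected)) {
    return(rep(as.integer(fallback), nrow(gm$dosages)))
  }
  desc <- s2$features$descriptors[s2$result$selected, , drop = FALSE]
  X <- features_from_descriptors(gm, desc)$values
  eta <- X %*% unname(s2$result$coefficients) + s2$result$intercept
  ifelse(as.numeric(eta) > 0, 1L, -1L)
}
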