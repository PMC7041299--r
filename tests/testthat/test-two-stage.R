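# Stage-1 / stage-2 orchestration and the final report.

test_that("a gene whose features all fail the filter yields an empty result", {
  set.seed(61)
  gm <- make_gm(matrix(rbinom(400 * 3, 2, 0.3), nrow = 400), orient = FALSE)
  phen <- phenotype(rep(c(1L, -1L), 200))
  res <- stage1_gene(gm, phen, "G", 1:3, fast_cfg(), seed = 1L)
  expect_null(res$selected_descriptors)
  expect_equal(res$gene_f1, 0)
})

test_that("a single-SNP gene can only produce single-SNP descriptors", {
  set.seed(62)
  y <- rep(c(1L, -1L), each = 150)
  d <- ifelse(y == 1L, rbinom(300, 2, 0.7), rbinom(300, 2, 0.3))
  gm <- make_gm(cbind(d), orient = FALSE)
  res <- stage1_gene(gm, phenotype(y), "G", 1L, fast_cfg(), seed = 1L)
  expect_false(is.null(res$selected_descriptors))
  expect_true(all(res$selected_descriptors$kind == "single"))
  expect_gt(res$gene_f1, 0)
})

test_that("stage-1 recovers a planted epistatic pair within its gene", {
  cfg <- sim_config(n_individuals = 2000L, n_snps = 20L,
                    n_target_pairs = 1L, seed = 63L)
  sim <- simulate_dataset(cfg, 1L)
  pair <- sim$truth$pairs[[1]]
  snps <- sort(unique(c(pair, pair + c(-1L, 1L))))
  snps <- snps[snps >= 1 & snps <= 20]
  res <- stage1_gene(sim$genotypes, sim$phenotype, "G", snps,
                     run_config(n_resamples = 200L), seed = 2L)
  d <- res$selected_descriptors
  expect_false(is.null(d))
  key <- descriptor_pair_keys(d)
  expect_true(any(key == pair_keys(sim$truth$pairs)))
  expect_gt(res$gene_f1, 0)
})

test_that("stage-2 candidate count is 9 per disjoint-gene single-SNP pair", {
  set.seed(64)
  n <- 400
  y <- rep(c(1L, -1L), each = n / 2)
  # two strongly associated single SNPs in different genes + one weak gene
  s1 <- ifelse(y == 1L, rbinom(n, 2, 0.6), rbinom(n, 2, 0.25))
  s2 <- ifelse(y == 1L, rbinom(n, 2, 0.55), rbinom(n, 2, 0.2))
  gm <- make_gm(cbind(s1, s2), orient = FALSE)
  phen <- phenotype(y)
  stage1 <- list(
    stage1_gene(gm, phen, "GA", 1L, fast_cfg(), seed = 3L),
    stage1_gene(gm, phen, "GB", 2L, fast_cfg(), seed = 4L)
  )
  expect_true(all(vapply(stage1, function(r) r$gene_f1 > 0, logical(1))))
  s2res <- stage2_cross(stage1, gm, phen, fast_cfg())
  n_single_pairs <- 1L  # one disjoint-gene SNP pair (snp1, snp2)
  expect_equal(s2res$n_candidates_prefilter, 9L * n_single_pairs)
  expect_equal(s2res$status, "ok")
})

test_that("a single admitted gene produces no cross-gene candidates", {
  set.seed(65)
  y <- rep(c(1L, -1L), each = 200)
  s1 <- ifelse(y == 1L, rbinom(400, 2, 0.6), rbinom(400, 2, 0.25))
  gm <- make_gm(cbind(s1), orient = FALSE)
  phen <- phenotype(y)
  stage1 <- list(stage1_gene(gm, phen, "GA", 1L, fast_cfg(), seed = 6L))
  s2res <- stage2_cross(stage1, gm, phen, fast_cfg())
  expect_equal(s2res$n_candidates_prefilter, 0L)
  expect_equal(ncol(s2res$features$values), s2res$n_carryover)
})

test_that("no admitted genes yields an explanatory empty stage-2 result", {
  set.seed(66)
  gm <- make_gm(matrix(rbinom(400 * 2, 2, 0.3), nrow = 400), orient = FALSE)
  phen <- phenotype(rep(c(1L, -1L), 200))
  stage1 <- list(stage1_gene(gm, phen, "GA", 1:2, fast_cfg(), seed = 7L))
  s2res <- stage2_cross(stage1, gm, phen, fast_cfg())
  expect_equal(s2res$status, "no_admitted_genes")
  rep_out <- build_report(s2res, phen)
  expect_equal(nrow(rep_out$features), 0L)
})

test_that("odds ratios come from the 2x2 table with Haldane correction", {
  y <- c(rep(1L, 50), rep(-1L, 50))
  phen <- phenotype(y)
  # feature with table [[40,10],[10,40]] -> OR = 16
  f1 <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  # feature with a zero cell [[5,0],[45,50]] -> Haldane-corrected, finite
  f2 <- c(rep(1, 5), rep(0, 95))
  fm <- episelect:::new_feature_matrix(
    cbind(f1, f2),
    data.frame(kind = "single", snp1_id = c("a", "b"), genotype1 = "Aa",
               snp2_id = NA, genotype2 = NA, genes1 = "G", genes2 = NA,
               cross_gene = FALSE, label = c("a_Aa", "b_Aa"),
               stringsAsFactors = FALSE)
  )
  stage2 <- structure(
    list(result = structure(
           list(frequencies = c(1, 1), selected = 1:2,
                coefficients = c(a_Aa = 2, b_Aa = 0.5), intercept = -1,
                lambda_grid = c(10, 1), refit_lambda = 1,
                descriptors = fm$descriptors),
           class = "stability_result"),
         features = fm, status = "ok"),
    class = "stage2_result"
  )
  rep_out <- build_report(stage2, phen)
  or1 <- rep_out$features$odds_ratio[rep_out$features$feature == "a_Aa"]
  or2 <- rep_out$features$odds_ratio[rep_out$features$feature == "b_Aa"]
  expect_equal(or1, 16)
  expect_equal(or2, (5.5 * 50.5) / (45.5 * 0.5))
  expect_true(is.finite(or2))
  expect_true(all(rep_out$features$sign_consistent))
  # rows sorted by chi-squared p
  expect_equal(rep_out$features$feature[1], "a_Aa")
})

test_that("the full two-stage run is deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 300L, n_snps = 12L, n_target_pairs = 1L,
                    seed = 67L)
  sim <- simulate_dataset(cfg, 1L)
  genes <- extend_promoter(
    assign_simulated_genes(12L, sim$truth$pairs, 6L, "within")
  )
  gmap <- assign_snps(sim$genotypes, genes)
  f1 <- run_two_stage(sim$genotypes, sim$phenotype, gmap, fast_cfg(seed = 9L))
  f2 <- run_two_stage(sim$genotypes, sim$phenotype, gmap, fast_cfg(seed = 9L))
  expect_identical(f1$report$features, f2$report$features)
  expect_identical(
    lapply(f1$stage1, `[[`, "gene_f1"),
    lapply(f2$stage1, `[[`, "gene_f1")
  )
})

test_that("reported weight signs agree with their odds ratios on simulation", {
  cfg <- sim_config(n_individuals = 1000L, n_snps = 10L, n_target_pairs = 1L,
                    seed = 68L)
  sim <- simulate_dataset(cfg, 1L)
  gmap <- assign_snps(sim$genotypes, extend_promoter(
    assign_simulated_genes(10L, sim$truth$pairs, 10L, "within")
  ))
  fit <- run_two_stage(sim$genotypes, sim$phenotype, gmap,
                       run_config(n_resamples = 100L, seed = 10L))
  feats <- fit$report$features
  expect_gt(nrow(feats), 0)
  nz <- feats[feats$weight != 0, ]
  expect_true(all((nz$weight > 0) == (nz$odds_ratio > 1)))
})

test_that("unpenalized covariates are appended to the final refit", {
  cfg <- sim_config(n_individuals = 500L, n_snps = 8L, n_target_pairs = 1L,
                    seed = 69L)
  sim <- simulate_dataset(cfg, 1L)
  gmap <- assign_snps(sim$genotypes, extend_promoter(
    assign_simulated_genes(8L, sim$truth$pairs, 8L, "within")
  ))
  set.seed(70)
  covar <- matrix(sim$phenotype$labels * 0.5 + rnorm(500, sd = 0.1),
                  ncol = 1, dimnames = list(NULL, "score"))
  fit <- run_two_stage(sim$genotypes, sim$phenotype, gmap,
                       run_config(n_resamples = 50L, seed = 11L),
                       covariates = covar)
  expect_false(is.null(fit$report$covariate_weights))
  expect_gt(fit$report$covariate_weights[["score"]], 0)
})
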