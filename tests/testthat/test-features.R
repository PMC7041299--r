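# Combinatorial encoding and quality filters.

test_that("one-hot encoding is exhaustive over genotypes and missingness", {
  gm <- make_gm(matrix(c(0L, 1L, 2L, NA), ncol = 1), orient = FALSE)
  oh <- one_hot(gm, 1L)
  expect_equal(unname(oh[1:3, ]), diag(3), ignore_attr = TRUE)
  expect_equal(unname(oh[4, ]), c(0L, 0L, 0L))
  expect_equal(colnames(oh), c("AA", "Aa", "aa"))
})

test_that("a monomorphic column fires only its AA indicator", {
  gm <- make_gm(matrix(0L, nrow = 5, ncol = 1), orient = FALSE)
  oh <- one_hot(gm, 1L)
  expect_equal(unname(colSums(oh)), c(5L, 0L, 0L))
})

test_that("interaction block activates exactly one of nine cells", {
  gm <- make_gm(cbind(c(1L, 0L, NA, 2L), c(2L, 1L, 1L, NA)), orient = FALSE)
  blk <- interaction_block(one_hot(gm, 1L), one_hot(gm, 2L))
  expect_equal(ncol(blk), 9L)
  # sample 1: (Aa, aa) -> only the Aaxaa cell
  expect_equal(sum(blk[1, ]), 1L)
  expect_equal(unname(blk[1, "Aaxaa"]), 1L)
  # either parent missing -> all nine zero
  expect_equal(sum(blk[3, ]), 0L)
  expect_equal(sum(blk[4, ]), 0L)
  # fully observed samples partition: row sums are exactly 1
  expect_equal(unname(rowSums(blk)[1:2]), c(1, 1))
})

test_that("gene design width follows 3k + 9k(k-1)/2", {
  set.seed(15)
  # polymorphic non-duplicating columns
  gm <- make_gm(matrix(rbinom(600, 2, 0.45), nrow = 60), orient = FALSE)
  for (k in c(1L, 2L, 5L)) {
    fm <- gene_feature_matrix(gm, seq_len(k), "G")
    expect_equal(ncol(fm$values), 3 * k + 9 * k * (k - 1) / 2)
    expect_equal(sum(fm$descriptors$kind == "single"), 3 * k)
  }
  fm1 <- gene_feature_matrix(gm, 1L, "G")
  expect_true(all(fm1$descriptors$kind == "single"))
  expect_error(gene_feature_matrix(gm, integer(0)), "at least one")
})

test_that("pair columns equal the product of their parent columns", {
  set.seed(16)
  gm <- make_gm(matrix(rbinom(300, 2, 0.4), nrow = 30), orient = FALSE)
  fm <- gene_feature_matrix(gm, 1:4, "G")
  d <- fm$descriptors
  for (p in which(d$kind == "pair")) {
    c1 <- fm$values[, d$label == paste0(d$snp1_id[p], "_", d$genotype1[p])]
    c2 <- fm$values[, d$label == paste0(d$snp2_id[p], "_", d$genotype2[p])]
    expect_equal(unname(fm$values[, p]), unname(c1 * c2))
  }
})

test_that("descriptor labels follow the RSID_genotype convention", {
  gm <- make_gm(cbind(c(0L, 1L, 2L, 0L, 1L, 2L), c(1L, 1L, 0L, 0L, 2L, 1L)),
                orient = FALSE)
  fm <- gene_feature_matrix(gm, 1:2, "G")
  expect_true("snp1_Aa" %in% fm$descriptors$label)
  expect_true("snp1_AA, snp2_Aa" %in% fm$descriptors$label)
  expect_equal(anyDuplicated(fm$descriptors$label), 0L)
})

test_that("genotype frequency counts missing samples in the denominator", {
  expect_equal(genotype_frequency(c(rep(1, 4), rep(0, 96))), 0.04)
  expect_equal(genotype_frequency(rep(1, 10)), 1)
  expect_equal(genotype_frequency(rep(0, 10)), 0)
})

test_that("chi-squared matches the hand-computed 2x2 value", {
  col <- c(rep(1, 50), rep(0, 50))
  phen <- phenotype(c(rep(1, 40), rep(-1, 10), rep(1, 10), rep(-1, 40)))
  # table [[40,10],[10,40]]: chi2 = 36, p = pchisq(36, 1, lower = FALSE)
  p <- chi2_pvalue(col, phen)
  expect_equal(p, pchisq(36, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p, 1.97e-9, tolerance = 0.01)
})

test_that("independence and degenerate margins give p = 1", {
  phen <- phenotype(rep(c(1, -1), each = 50))
  balanced <- rep(rep(c(1, 0), each = 25), 2)  # [[25,25],[25,25]]
  expect_equal(chi2_pvalue(balanced, phen), 1)
  expect_equal(chi2_pvalue(rep(1, 100), phen), 1)
})

test_that("vectorized chi-squared agrees with chisq.test per column", {
  set.seed(21)
  y <- rep(c(1L, -1L), each = 40)
  X <- matrix(rbinom(80 * 25, 1, 0.35), nrow = 80)
  got <- episelect:::chi2_pvalues(X, y)
  want <- apply(X, 2, function(col) {
    if (length(unique(col)) == 1L) return(1)
    suppressWarnings(chisq.test(table(col, y), correct = FALSE)$p.value)
  })
  expect_equal(got, unname(want), tolerance = 1e-10)
})

test_that("filters use strict thresholds and are idempotent", {
  y <- rep(c(1L, -1L), each = 50)
  phen <- phenotype(y)
  # column at frequency exactly 0.05 and perfectly predictive at 0.3
  at_bound <- c(rep(1, 5), rep(0, 95))
  strong <- as.integer(y == 1L & seq_along(y) <= 30)
  fm <- episelect:::new_feature_matrix(
    cbind(at_bound, strong),
    data.frame(kind = "single", snp1_id = c("a", "b"),
               genotype1 = "Aa", snp2_id = NA, genotype2 = NA,
               genes1 = "G", genes2 = NA, cross_gene = FALSE,
               label = c("a_Aa", "b_Aa"), stringsAsFactors = FALSE)
  )
  kept <- filter_features(fm, phen, 0.05, 0.01)
  expect_equal(kept$descriptors$label, "b_Aa")  # bound column removed
  kept2 <- filter_features(fm, phen, 0.05, 1e-5)
  expect_equal(kept2$descriptors$label, "b_Aa")  # survives stage-2 threshold
  again <- filter_features(kept, phen, 0.05, 0.01)
  expect_equal(again$descriptors$label, kept$descriptors$label)
  expect_equal(unname(again$values), unname(kept$values))
})

test_that("filter retention matches a per-column recomputation oracle", {
  set.seed(31)
  y <- rep(c(1L, -1L), each = 60)
  phen <- phenotype(y)
  X <- matrix(rbinom(120 * 50, 1, runif(50, 0.02, 0.5)), nrow = 120,
              byrow = TRUE)
  desc <- data.frame(kind = "single", snp1_id = sprintf("s%d", 1:50),
                     genotype1 = "Aa", snp2_id = NA, genotype2 = NA,
                     genes1 = "G", genes2 = NA, cross_gene = FALSE,
                     label = sprintf("s%d_Aa", 1:50),
                     stringsAsFactors = FALSE)
  fm <- episelect:::new_feature_matrix(X, desc)
  kept <- filter_features(fm, phen, 0.05, 0.01)
  oracle <- which(vapply(seq_len(50), function(j) {
    freq <- mean(X[, j])
    p <- if (length(unique(X[, j])) == 1L) 1 else {
      suppressWarnings(chisq.test(table(X[, j], y),
                                  correct = FALSE)$p.value)
    }
    freq > 0.05 && p < 0.01
  }, logical(1)))
  expect_equal(match(kept$descriptors$label, desc$label), oracle)
})

test_that("feature matrices export as CSV with descriptor headers", {
  gm <- make_gm(cbind(c(0L, 1L, 2L, 1L), c(1L, 1L, 0L, 2L)), orient = FALSE)
  fm <- gene_feature_matrix(gm, 1:2, "G")
  path <- tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 4L)
  expect_true("snp1_Aa" %in% names(tab))
})
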