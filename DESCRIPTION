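Package: episelect
Title: Two-Stage Discovery of Within-Gene and Cross-Gene Epistasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene-based discovery of SNP-SNP interactions (epistasis)
    associated with a binary phenotype. Genotypes are grouped by gene
    (transcript span plus a 1 kb upstream promoter), pruned by linkage
    disequilibrium (Lewontin's D' and r^2 with EM haplotype-frequency
    estimation), expanded into one-hot genotype indicators and nine-term
    pairwise interaction indicators, filtered by genotype frequency and
    chi-squared association, and modeled by L1-regularized logistic
    regression with stability selection, first within each gene, then
    across genes by crossing the selected single-SNP features. Includes
    readers and writers for VCF and PLINK genotype formats, nested
    (double) cross-validation for honest performance estimates, and a
    seeded simulator of pure (marginal-effect-free) epistatic
    case-control datasets with known penetrance-table ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    vcfR,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
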