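---
title: "Two-stage epistasis discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage epistasis discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`episelect` discovers SNP–SNP interactions (epistasis) associated with a
case/control phenotype by a gene-based, two-stage sparse-modeling workflow.
This vignette is the package's account of the underlying statistics: what is
modeled, which knobs matter, what the bundled simulator does and does not
emulate, and where the design was genuinely open.

## The model

Genotypes are coded as minor-allele dosages; a SNP with minor allele *a*
has genotypes AA, Aa, aa. Each SNP is one-hot expanded into three binary
indicators, and each unordered SNP pair contributes the nine elementwise
products of its indicator triplets. For a gene with $k$ SNPs the design
matrix is

$$y = \alpha_0 + \sum_{i=1}^{k} \alpha_i \,\mathrm{SNP}_i
      + \sum_{i<j} \alpha_{\mathrm{int}(i,j)} \,\mathrm{SNP}_i \otimes \mathrm{SNP}_j ,$$

with $3k + 9k(k-1)/2$ binary columns. Features are selected by
L1-regularized logistic regression on labels $y_\ell \in \{-1,+1\}$,

$$\hat\alpha^\lambda = \arg\min_{\alpha, c}
  \sum_{\ell=1}^{n} \log\!\left(1 + e^{-y_\ell (\mathbf{x}_\ell^\top \alpha + c)}\right)
  + \lambda \lVert \alpha \rVert_1 ,$$

fitted via `glmnet` (whose deviance is scaled by $1/n$; the package keeps
$\lambda$ on the sum-loss scale above and converts by $n$). Because
correlated indicator features make the L1 solution non-unique, selection is
stabilized by resampling: 500 class-stratified half-samples are drawn
without replacement, the path is refitted on each, and only features that
are selected in a large fraction of rounds are retained.

Stage 1 runs this per gene; genes whose refitted model has non-zero
stratified 2-fold CV F1 are admitted. Stage 2 pools the admitted genes'
selected features, generates nine-term interaction candidates for every
pair of pooled *single-SNP* features whose gene sets are disjoint (selected
within-gene pairs are carried along but not re-crossed), filters, and runs
the same selection once more. The final model is an L1 refit on the
selected set with $\lambda$ chosen by an internal stratified 2-fold CV.

## Parameters and defaults

| parameter | default | role |
|---|---|---|
| promoter length | 1000 bp | upstream, strand-aware extension of the gene span |
| LD thresholds | D′ > 0.9 and r² > 0.9 | both strict; blocks are transitive closures |
| LD window | 1000 adjacent SNPs | LD is local; full-window equals all-pairs |
| genotype frequency | > 0.05 | strict; proportion over **all** samples |
| χ² threshold, stage 1 | p < 0.01 | per binary feature, 2×2 table, 1 df, no continuity correction |
| χ² threshold, stage 2 | p < 10⁻⁵ | applied to new cross-gene candidates |
| resampling rounds | 500 | stability-selection randomizations |
| subsample fraction | 0.5 | without replacement, class-stratified |
| λ grid | 10 points, 3 decades below λ_max | λ_max computed from the data |
| selection region | top decade of the path | where per-round selection is counted |
| per-round cap | ⌈√(0.8 p)⌉ | first path entrants counted per round |
| selection threshold | 0.6 | minimum selection frequency |

The frequency filter protects against indicators so rare that their 2×2
tables are unstable; the χ² filters remove features with no marginal
association before any multivariate modeling (and are the reason the
workflow cannot see interactions whose *marginals* are null — see
Limitations).

### The stability-selection schedule

The per-round selection rule is the one genuinely open design decision, and
it matters. If a feature counts as "selected in a round" whenever it is
nonzero *anywhere* on a long λ path, the per-round support at the weakly
penalized end contains essentially every pre-filtered feature, selection
frequencies saturate at 1, and the procedure degenerates into "keep
everything that passed the χ² filter" — measurably *worse* than a single
CV-tuned L1 fit on false positives. Informative frequencies require sparse
per-round supports. The package therefore counts selection only over the
strongly penalized top decade of the path and, within it, only for the
first $q = \lceil\sqrt{0.8\,p}\rceil$ features to enter — the standard
stability-selection sizing, which bounds the expected number of stably
selected false positives near one for thresholds above 0.5. The retention
threshold of 0.6 sits in the canonical (0.5, 1) range. With this schedule
the package's simulation study shows the intended behaviour: the mean and
variance of false-positive interaction features drop several-fold relative
to the plain CV-tuned fit (`method = "plain"` reproduces that comparison).

### Other resolved design points

* **Allele orientation** is recomputed from the loaded cohort (minor =
  less frequent), not taken from REF/ALT or file allele order; ties at 0.5
  keep input orientation.
* **Missing genotypes** are kept as `NA` at I/O level; one-hot encoding
  maps them to an all-zero indicator row, so a missing genotype simply
  fires no feature. Frequencies use all samples in the denominator.
* **Coordinates** are 1-based inclusive internally (matching VCF/BIM);
  BED input is converted on read. Overlapping genes duplicate their shared
  SNPs — stage 1 treats genes independently, so duplication is harmless,
  and "cross-gene" is defined as *disjoint gene-label sets*, so a SNP
  shared by overlapping genes never pairs with itself.
* **Two-locus haplotype frequencies** for D′/r² come from an EM over the
  double-heterozygote phase ambiguity, initialized at linkage-equilibrium
  products — deterministic, and exact whenever no double heterozygotes are
  present (the tests pin that case to a closed-form counting oracle).
  Monomorphic loci are flagged degenerate and never linked into blocks.
* **Gene admission** uses stratified 2-fold CV F1 of the refitted gene
  model rather than training-set F1, tempering the admission bar's
  optimism. Note that a random classifier on balanced data has F1 near
  0.5, so "non-zero F1" is a deliberately permissive gate; the pruning
  burden lies with stage 2's selection.
* **Stage-2 filtering** applies the 10⁻⁵ χ² threshold to newly generated
  cross-gene candidates only; carried-over stage-1 features were already
  filtered at 0.01. A switch (`stage2_filter_carryover`) enables the
  stricter reading.
* **Covariates** (e.g. clinical scores) join the final refit unpenalized
  and are never subject to stability selection.
* **Internal 2-fold CV** is implemented directly over `glmnet` path fits
  (deterministic stratified folds) because `cv.glmnet` requires at least
  three folds.
* **Degenerate fits**: interaction columns identical to a parent indicator
  are dropped (keeping the simpler descriptor); designs whose usable
  columns are all constant on a subsample yield an empty round rather than
  an error; a CV fold with fewer than two members of a class falls back to
  the middle of the λ grid.

## The simulator

`simulate_dataset()` emulates GAMETES-style pure-epistasis data. A target
SNP pair carries a 3×3 penetrance table $f$ over joint genotypes that is
*marginal-effect-free*: under Hardy–Weinberg genotype probabilities
$P(g_1), P(g_2)$ at the target MAF, every row and column of $f$ has
probability-weighted mean equal to the prevalence $K$, so each single locus
is exactly independent of disease status. Heritability is defined on the
binary-trait variance scale,

$$h^2 = \sum_{g} P(g)\,(f(g) - K)^2 \,/\, K(1-K).$$

Tables are drawn by rejection: a random 3×3 matrix is projected onto the
marginal-free affine set (probability-weighted double-centering), its
deviations rescaled to hit $h^2$ exactly, and the draw is repeated until
all penetrances fall in $[0,1]$; infeasible (MAF, $h^2$, K) combinations
error with the bound named. Defaults mirror the study conditions the
package validates against: 2000 individuals, case/control ratio 1, 100
SNPs, target MAF 0.2, $h^2 = 0.2$, prevalence 0.5 (which makes balanced
class-rejection sampling efficient). Multi-pair ("combined") datasets use
heterogeneity: each individual's status is governed by one pair model,
assigned uniformly — which attenuates each pair's detectable signal to
roughly $h^2/3$ in the pooled data. Noise SNPs are Hardy–Weinberg with MAF
uniform in (0.05, 0.5), independent of status. Synthetic gene tables bin
consecutive SNPs (10 per gene by default) with target pairs placed either
within one gene or across two.

What the simulator does **not** emulate: LD structure among noise SNPs,
missing genotypes, genotyping error, population stratification, covariate
effects, or quantitative traits. Passing the simulation study therefore
demonstrates correct mechanics and the statistical properties of the
selection engine under clean conditions — not robustness to the artifacts
of real cohorts.

## Known limitations

* **Cross-gene *pure* epistasis is invisible by construction.** The
  stage-1 χ² filter admits only marginally associated features, and stage 2
  builds cross-gene candidates exclusively from stage-1 survivors. A
  marginal-effect-free pair split across two genes presents *null* single-
  SNP features in both genes ($P(\text{case}\mid g_1) = K$ for every
  $g_1$), so its interaction can essentially never be assembled — each
  target SNP would have to pass a p < 0.01 filter on pure chance. The
  package's own simulation confirms ~0% recovery in the "across"
  placement, while the same three-pair datasets in "within" placement are
  recovered reliably. Cross-gene discovery is effective precisely for
  interactions whose loci carry at least some marginal signal.
* Only pairwise interactions are modeled; higher-order epistasis is out of
  scope.
* The strict filters favour precision over recall: with small samples the
  workflow returns few, well-supported features and will miss weak true
  positives.
* Per-gene designs are materialized densely; genes with very many SNPs
  (thousands after LD reduction) are memory-hungry.

## Problem sizes used by the test suite

The package's validation runs at the study conditions (n = 2000, 100 SNPs,
MAF 0.2, h² 0.2, ratio 1) with 20 replicates per claim in the test suite
and 10 in `scripts/acceptance.R`; unit tests use smaller seeded instances
(n = 60–800) with reduced resampling rounds, chosen so that the whole
suite runs in minutes on a single CPU while the headline claims are still
measured under the full conditions.
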