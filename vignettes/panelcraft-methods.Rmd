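---
title: "panelcraft: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panelcraft: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcraft)
```

panelcraft implements the computational side of building and using a
targeted-genotyping SNP array for a diverse, partly hybrid plant germplasm
collection: selecting panel SNPs from population resequencing variants,
choosing minimal fingerprinting marker sets, characterizing population
structure, scanning for trait associations with a mixed linear model, and
evaluating genomic prediction. This vignette records the models, the
numerical choices, and the reasoning behind design decisions that the
function reference does not cover.

## Shared data model

All modules exchange genotypes as a samples-by-SNPs integer matrix of
diploid alternate-allele dosages (0/1/2, `NA` = missing) inside a
`variant_table`, together with per-SNP records (chromosome, 1-based position,
ref/alt alleles, site quality). Coordinates are 1-based and inclusive
everywhere, matching VCF and GFF3. Phased separators (`|`) are read as
unphased; polyploid GT fields are rejected with an error rather than
collapsed, because dosage coding and every downstream estimator here assume
diploidy. Readers never impute: missingness handling is an explicit,
per-method decision (pairwise-complete for distances and kinship, column-mean
imputation for PCA, LD r^2, association scans and prediction).

## The panel-design funnel

`design_panel()` applies four stages to the resequencing stream, mirroring
standard array-design practice:

1. **Site quality** (`filter_variants()`): missing rate < 0.2, site QUAL >=
   50, MAF >= 0.15, and removal of SNPs on sequences outside the supplied
   chromosome set (unplaced contigs). Site QUAL is used as the quality
   predicate; per-genotype GQ is not consulted.
2. **Flank QC and redundancy** (`flank_qc()`, `uniqueness_check()`): the
   201 bp region around each SNP (100 bp per side) must have GC in
   [0.4, 0.6], contain no N, and align nowhere else in the genome at >= 60%
   identity over >= 60% of its length. SNPs whose flanks are truncated by a
   chromosome end fail: fixed-length capture probes need complete flanks.
3. **Probe windows** (`probe_windows()`): all 100 bp windows at 1 bp steps
   across the 301 bp region (150 bp per side) are scored for GC, N-freedom
   and uniqueness; a SNP survives if any window qualifies. Windows are not
   required to contain the SNP — capture probes can hybridize adjacent to the
   variant — but the chosen probe prefers SNP-containing windows, then GC
   closest to 0.5, then the leftmost start.
4. **LD pruning** (`ld_prune()`): sliding windows of 100 kept SNPs, step 10,
   greedy removal until no in-window pair exceeds r^2 = 0.2. Within a window
   the worst pair repeatedly loses its lower-MAF member (ties: the
   higher column index), and passes repeat until the bound holds on the
   final kept set — a deterministic rule whose post-condition is verified
   exhaustively in the tests.

The linkage-map stream is cross-referenced against the resequencing variants
on (chromosome, position, ref, alt) and then passed through the same flank
and probe screens; `assemble_panel()` takes the deduplicated union, merging
source labels on collisions and refusing conflicting alleles at a locus.
Stage counts are recorded so a funnel report can be emitted.

### The redundancy alignment engine

The uniqueness filter is a seed-and-extend screen: exact 15-mers anchor
ungapped diagonal alignments on both strands, identity is computed over the
aligned span, and any non-self alignment with span >= 0.6 of the region at
identity >= 0.6 marks the region as a duplicate. "Similarity >= 60% over
more than 60% of the sequence" is interpreted as span-coverage AND
identity-over-span, the strictest of the readings consistent with a local
aligner. Two consequences are worth knowing. First, like BLAST-style tools,
copies diverged enough to contain no exact seed k-mer cannot be found; at
60-70% identity this is a real blind spot, while the high-identity
duplicates the filter exists for (recent segmental duplications) virtually
always contain seeds. Second, plus-strand alignments overlapping the
region's own locus are discounted as self-hits. The engine is validated
against an exhaustive sliding-window aligner on small genomes, where the two
agree exactly on planted duplicates, random sequence, and constructed
50%-identity copies.

For whole-region and per-window checks at scale, seed diagonals are computed
once per 301 bp region and every window is scored on each diagonal by sliding
sums, which makes the funnel roughly two orders of magnitude faster than
per-window re-seeding with identical results.

## Fingerprinting

`discrimination_matrix()` records, per candidate SNP, the set of unordered
sample pairs with unequal non-missing genotype codes; a heterozygote differs
from both homozygotes, and a missing call never distinguishes.
`greedy_core_set()` is classical greedy set cover (pick the SNP covering the
most residual pairs; ties go to the lower locus index), stopping at full
coverage or an optional size cap. Greedy was chosen because the reference
workflow's software documents no algorithm and greedy carries the standard
ln(n) approximation guarantee; `exact_core_set()` provides the exhaustive
minimum for instances of up to ~20 candidates and is used as the test
oracle. KASP-style candidate pre-filtering demands zero missingness,
MAF >= 0.15, exonic position and flank QC; thermodynamic primer screening is
out of scope, so flank QC stands in as the designability proxy.

## Population genetics

* `p_distance()`: mean per-site dosage dissimilarity `|g_i - g_j| / 2` over
  co-observed sites — 0 for identical samples, 1 for opposite homozygotes at
  every site. The distance tool cited by array workflows does not document
  its exact normalization, so this definition is stated explicitly and
  tested against its own brute-force oracle.
* `nj_tree()`: Saitou-Nei neighbor joining, implemented in-package so the
  tie rule (lowest index pair) and the negative-branch policy (clamp to
  zero, move the deficit to the sister branch) are explicit and
  deterministic; random distance matrices are cross-checked against
  `ape::nj()` and additive trees are recovered exactly.
* `pca_genotypes()`: SVD of column-centered, mean-imputed dosages, with a
  fixed sign convention (largest-|loading| entry positive).
* `nucleotide_diversity()`: per site `2 p q n/(n-1)` on the group's allele
  counts, averaged over sites.
* `fst_weir_cockerham()`: the two-population Weir-Cockerham variance
  component estimator, combined across sites as a ratio of sums (stable for
  rare variants, the standard choice); negative estimates are reported, not
  clipped. A hand-computed single-site fixture pins the arithmetic.

Bootstrap support for NJ trees resamples SNP columns (default 100
replicates, a desk-scale default where published trees often use 1000).
Model-based admixture inference is deliberately absent; group labels come
from the user or from clustering on PCA coordinates.

## Mixed-model association scan

The scan follows the EMMAX approximation. The kinship is the simple
matching coefficient: the mean over co-observed sites of 1, 0.5 or 0 for
genotype pairs differing by 0, 1 or 2 alt alleles — the named coefficient
leaves diploid scoring open, so this choice is isolated in `smc_kinship()`.
Variance components of `y = X b + u + e`, `Var(u) = s_g^2 K`, are estimated
once under the null by REML: the kernel is spectrally decomposed after
projecting out the fixed effects and the restricted likelihood is maximized
over the log variance ratio with a 49-point bracketing grid plus Brent
refinement (tolerance 1e-8); the implementation reproduces a from-scratch
restricted-likelihood grid to three decimals in h^2. Each SNP then gets a
generalized least squares Wald t-test with the variance structure held
fixed; with K = I this reduces exactly (to 1e-8 and beyond) to per-SNP OLS,
which the tests assert. Covariates default to the first 3 genotype PCs.
The significance threshold is the effective-test rule: `log10(N)` with N the
LD-pruned (r^2 = 0.1) marker count, optionally capped by a configured
working threshold (the working threshold is never raised above the computed
one). Genotype-class trait differences use one-way ANOVA plus pairwise
Welch t-tests with conventional stars; "haplotypes" at a hit are single-SNP
genotype classes. Pairwise LD is computed from two-locus haplotype
frequencies by EM on unphased genotypes (D, D', r^2), with the composite
dosage-correlation r^2 as a fallback when the EM degenerates, and haplotype
blocks are reported as maximal runs of adjacent-pair D' >= 0.98 — a
threshold-run simplification of block calling.

## Genomic prediction

`vanraden_grm()` builds the method-1 genomic relationship matrix
`M M' / (2 sum p(1-p))` from mean-imputed, 2p-centered dosages (plus a 1e-8
diagonal ridge). `gblup()` reuses the spectral REML kernel and returns
variance components, `H^2 = s_g^2/(s_g^2+s_e^2)`, BLUP breeding values and a
predictor for held-out individuals (`s_g^2 K_cross V^-1 (y - X b)`). The
central correctness oracle is the GBLUP/RR-BLUP identity: GEBVs equal ridge
marker-effect predictions at the matched shrinkage to 1e-6 on every random
fixture.

The Bayes alphabet samplers (compiled, single pass per iteration over
markers) share one Gibbs kernel: BayesA gives every marker its own
scaled-inverse-chi-square variance; BayesB adds a point mass at zero with
prior exclusion probability pi0 = 0.99; BayesC uses a common slab variance.
Hyperscales follow the usual heuristic — prior df 5 and scales chosen so the
implied marker variance matches R^2 = 0.5 of the phenotypic variance
(divided by the inclusion probability for B/C). Chains use R's RNG, so a
seed reproduces a chain bit-for-bit. Desk-scale defaults are 3000 iterations
with 500 burn-in and 10 cross-validation repeats; published protocols often
use 100 repeats, and both are reachable by argument.

`cross_validate()` performs repeated k-fold CV (default 5-fold) with
disjoint random folds per repeat; the training fit never sees held-out
phenotypes (a poisoning test asserts bit-identical training fits), and
predictive ability (PA) is the Pearson correlation of observed phenotypes
with predictions in the held-out fold. Prediction accuracy is
`PC = PA / sqrt(H^2)`. GWAS hits can be promoted to fixed effects
(`integrate_fixed_effect_snps()`); their columns are removed from the
random-effect marker set so their variance is not counted twice, and
collinear columns are dropped with a warning.

## The synthetic-data generator

`sim_config()` defaults describe the emulated study: 220 accessions in four
population clusters, a 15-chromosome genome, panel-scale marker density, a
Balding-Nichols divergence target of 0.25 (the observed between-cluster
range), and moderately heritable traits (default target 0.35, the middle of
the 0.25-0.45 range typical of leaf morphology). Chromosomes default to
200 kb — large enough for flank/probe geometry and thousands of sites, small
enough that the full funnel runs in seconds. Subpopulation allele
frequencies are drawn from the Balding-Nichols distribution around a
Beta-distributed ancestral frequency; this is an emulation chosen because it
hits an F_ST target in expectation, not a claim about any real population's
history. Phenotypes are `y = W beta + e` with i.i.d. normal effects at
sampled QTN (or at every polymorphic locus, the infinitesimal regime) and
the residual rescaled so the realized variance ratio equals the target h^2
exactly — the study this emulates reports only estimated heritabilities, so
exactness here buys sharper recovery tests.

Linkage disequilibrium is available through block-copied founder haplotypes
(`ld_block_bp`, founder pool per block) but defaults to off, for two
reasons: panel-scale SNPs average >100 kb apart, where background LD is
weak; and founder-pool LD is shared ancestry, which inflates
Weir-Cockerham F_ST relative to the Balding-Nichols target — with
independent sites the estimator recovers the target within ±0.05. Planted
duplicate segments (recorded coordinates, configurable length and per-base
identity, non-overlapping) give the redundancy filter known positives.

What the generator does not emulate — and what passing tests therefore do
not establish about real data — includes realistic recombination and LD
decay, allele-frequency spectra shaped by selection or bottlenecks,
genotyping error correlated with probe performance, polyploidy, and
family structure beyond single F1 crosses.

## Calibration expectations and problem sizes

Two statistical facts shape the test and acceptance designs:

* The sampling error of GRM-based heritability estimates for unrelated
  individuals is roughly `sqrt(2 m_eff) / n`. At the recovery design used
  here (n = 400, m = 4000) that is ~0.2 per replicate, so recovery is
  asserted on the mean of 10 independent simulations (tolerance 0.10), and
  the null-variance checks use designs with n >> m where the boundary
  estimate concentrates near zero. Sparse-QTN traits under unlinked markers
  additionally attenuate SNP heritability slightly — a known property of
  GRM misspecification, visible in the recovery means.
* The achievable PA at a fixed h^2 varies with the realized polygenic
  effects (their alignment with the GRM eigenstructure), not only with fold
  noise, so the PA-vs-h^2 relationship is measured by averaging CV PA over
  several phenotype draws per h^2 point before correlating.

Problem sizes used by the test suite and the acceptance script (hundreds of
samples, hundreds to a few thousand markers, 10-20 seeds per stochastic
claim) were chosen so each statistical assertion has comfortable power while
the whole suite stays interactive.

## Known limitations

* The uniqueness filter's sensitivity floor is set by exact 15-mer seeding
  (see above); a vendor aligner with gapped extension would find more
  marginal duplicates.
* The EMMAX approximation holds variance components fixed across SNPs; for
  very large effects an exact per-SNP REML would give slightly different
  tails.
* Bayes-alphabet hyperparameters are fixed heuristics; pi is not estimated.
* `read_gff()` keeps one gene model per gene (union of features via Parent
  chains); multi-isoform annotations are collapsed.
* The NJ implementation is quadratic-cubic in taxa and intended for
  hundreds, not tens of thousands, of samples.
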