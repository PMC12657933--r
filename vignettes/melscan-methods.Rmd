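---
title: "Methods: from fermentation phenotypes to multiple-effect loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fermentation phenotypes to multiple-effect loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inbred crop diversity panels — here modeled on a common-bean panel of 299
lines from two landraces (Durango, Mesoamerica) subdivided into six market
classes — vary in the biochemical composition of their seed. When milled,
digested seed is fermented in vitro by human fecal microbiomes, the
resulting taxa abundances, diversity metrics and short-chain fatty acid
(SCFA) concentrations become quantitative phenotypes of the *plant*
genotype. `melscan` implements the computational chain that links SNP
variation in such a panel to these fermentation phenotypes: trait
processing, community statistics, construction of polymicrobial score
variables, mixed-model heritability filtering and BLUP estimation, a
genome-wide association scan, and the calling of multiple-effect loci
(MEL) — genomic intervals whose variation shifts many microbiome traits
across two or more donor microbiomes.

Because the package is exercised entirely on synthetic data, every stage is
validated by parameter recovery: the simulator plants known pleiotropic
loci and the pipeline must find them (and must find nothing when nothing
was planted).

## Trait processing

Counts are rarefied to an even depth (default 7,197 reads) by sampling
reads without replacement; samples below depth are dropped with a warning.
Features are filtered within donor ("by subject") on two floors: detection
in at least 10% of samples and mean relative abundance of at least 0.15%.
The filter order is rarefy, then filter; both parameters and the order are
recorded in the table's provenance. Whether abundance filtering should
precede rarefaction is genuinely ambiguous; we chose this order because the
prevalence floor is defined on the rarefied detection pattern.

Two transforms produce trait matrices: `log2(count + 1)` for per-taxon GWAS
traits, and the centered log-ratio (CLR) for compositional analyses,
`clr(x)_i = ln x_i − mean_j ln x_j`. Zeros are handled differently in the
two paths — a pseudocount of 1 for the log2 traits, multiplicative
replacement (0.5 counts, then re-closure) for CLR — because CLR requires
strictly positive parts while the log2 traits only need boundedness at
zero. Both choices are configurable and recorded.

Alpha diversity offers Shannon (base e by default; base 2 available since
toolchains differ), Gini–Simpson, Pielou evenness, observed features and
bias-corrected Chao1 (`S + F1(F1−1)/(2(F2+1))`, defined even when no
doubletons exist). Faith's phylogenetic diversity is out of scope: no stage
downstream consumes a phylogeny.

## Community statistics

Bray–Curtis dissimilarities (via `vegan`) feed three analyses: principal
coordinates (classical scaling; negative eigenvalues are reported, never
silently dropped), the mean distance of each fermented sample from its
donor's substrate-free blank wells, and a one-way PERMANOVA. The PERMANOVA
pseudo-F follows Anderson's among/within partition of squared
dissimilarities and the p-value uses greater-or-equal counting with +1
smoothing, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so 999 permutations give a
minimal attainable p of 0.001. Univariate group tests are Kruskal–Wallis
with Benjamini–Hochberg adjustment across the trait family, followed by
Dunn's tie-corrected post hoc z tests (BH across pairs, matching the
trait-level adjustment; the pairwise adjustment had to be chosen here, and
consistency with the family-level procedure was the deciding argument).
Spearman correlations use midranks with the large-sample t approximation.

## Polymicrobial score variables

The core genera — the most abundant genera jointly covering ≥ 90% of the
community — are CLR-transformed and fed to a sequential (Type-I) MANOVA
with fixed effects in the order genotype, digestion batch, plate within
batch. Blank wells are excluded: they carry no genotype and would distort
the genotype SSCP. The decomposition yields hypothesis
sums-of-squares-and-cross-products (SSCP) matrices per term and an error
SSCP; dividing by degrees of freedom gives mean-square (covariance)
matrices, and correlations follow by standardization.

The *genetic* covariance matrix is solved from expected mean squares, the
multivariate analog of the one-way variance-component solve:
`Σ_G = (M_H − M_E) / c`, with `c = r` for balanced r-replicate designs and
`c = (N − Σ n_i²/N)/(g − 1)` under unbalanced replication (the partially
replicated design is unbalanced by construction). `Σ_G` is a difference of
matrices and need not be positive semidefinite; its eigendecomposition is
used as-is, with an optional nearest-PSD projection flag (off by default)
for users who need a proper covariance.

Canonical discriminant analysis solves `H a = λ E a`, maximizing
among-genotype relative to within-genotype variation. Raw coefficients are
scaled to unit within-group variance (`a'(E/df_E)a = 1`); standardized
coefficients multiply by the within-group standard deviations. Because CLR
rows sum to zero, `E` is rank-deficient by one; a relative ridge
(`ε·trace(E)/p`, ε = 1e-8, escalated only as far as needed for a
well-conditioned Cholesky) restores identifiability and is logged whenever
applied.

Scores are linear combinations of the CLR values: covariance-derived and
raw-CDA loadings apply to centered columns, correlation-derived and
standardized-CDA loadings to centered-and-scaled columns. Four components
from each of four PCA sources (hypothesis covariance/correlation, genetic
covariance/correlation) plus four raw and four standardized canonical
components give the 24 score variables (16 PCA-derived, 8 CDA-derived),
named `HypCovPC1`…`GenCorrPC4`, `RawCD1`…`StdCD4`. All eigenvectors carry a
deterministic sign convention (largest-magnitude entry positive) so scores
reproduce across runs.

## Mixed model, heritability, BLUPs

Each trait is modeled as
`y = Xβ + Z_g u_g + Z_batch u_b + Z_plate u_p + Z_row u_r + Z_col u_c + e`,
with `u_g ~ N(0, K σ²_g)` structured by the centered kinship matrix
(`K = WW'/s`, `W` column-centered dosages, `s` scaling the mean diagonal to
1) and the first three genotype principal components as fixed covariates.
Rows and columns are nested within plate. The kinship matrix enters as the
covariance of the genotype random effect — the standard genomic-BLUP
construction. Estimation is EM-REML on Henderson's mixed-model equations
after absorbing `K` by its Cholesky factor; variances are floored at a tiny
multiple of the trait variance, convergence is declared at a relative
parameter change below 1e-6 (cap 500 iterations), and non-convergence is
reported, never silent. The restricted likelihood is computed each
iteration from mixed-model-equation identities and is non-decreasing — a
property the tests assert.

Broad-sense heritability is the conservative ratio
`H² = σ²_g / (σ²_g + σ²_batch + σ²_plate + σ²_row + σ²_col + σ²_e)`
on the observation scale, with no line-mean transformation. Traits with
`H² ≥ 0.1` are retained by default; the boundary convention is a flag
because the quoted rule is stated both as "exclude < 0.1" and "filter
> 0.1" in the source material for this kind of analysis.

## Association scan and MEL calling

The scan regresses per-line BLUPs on intercept, the first five genotype
PCs and the SNP dosage, taking the Wald p of the dosage term; missing
dosages fall back to per-SNP complete-case fits, and SNPs monomorphic or
collinear after missingness are flagged rather than tested. Significance is
`p < α/m` (Bonferroni over the tested SNPs); LOD = −log10(p) is reported
but not used as a second gate, because at m = 132,314 the threshold
α/m = 3.8e-7 corresponds to LOD 6.42, and a joint "LOD > 6.5" gate would be
internally inconsistent with it.

A conditioned scan iterates the marginal scan with pseudo-QTN covariates:
Bonferroni-significant SNPs are binned (1 Mb), the best per bin kept,
candidates in LD (r² ≥ 0.7) with a kept candidate pruned, the set capped at
10, and the scan repeated with the kept dosages as fixed covariates —
excluding, for each tested SNP, any pseudo-QTN in the tested SNP's own bin
so a signal is never conditioned on itself. Iteration stops when the
pseudo-QTN set repeats. This preserves the core mechanism of multi-locus
iterative scans (conditioning with bin-based exclusion) in a fully
specified form; the marginal scan remains available as the default
pipeline flag.

MEL calling bins significant associations into 0.1 Mb half-open intervals
(`[k·10⁵, (k+1)·10⁵)`; a boundary SNP belongs to the upper bin). Seed bins
need at least 5 contributing traits — counted as distinct (donor, trait)
pairs by default, with distinct-trait-name counting as a flag — from at
least 2 donors. Boundaries grow from the seed bin's significant SNPs to
every SNP within a 5 Mb search window in LD r² ≥ 0.75 with any of them,
regardless of distance; the interval spans the boundary set, overlapping
intervals merge with provenance retained, and a stringent tier annotates
regions with more than 15 contributing pairs. LD is the squared Pearson
correlation of dosage vectors over jointly non-missing lines — exact for
inbred homozygous coding, where dosage correlation equals gametic
correlation.

Allelic-effect summaries (per-genotype-class n/mean/SD, overall and by
market class), log2 fold changes of relative abundance with a 1e-6
pseudocount, and sign/rank concordance between a mapping panel and a
validation or complementation experiment complete the module.

## The synthetic-data generator

The generator defines the study conditions the tests run under; it is not
a tuning surface.

**Genotypes.** Two landraces (defaults 198 + 101 = 299 lines; market
classes nest within landraces with fixed proportions) drawn from a
Balding–Nichols model: ancestral frequencies Uniform(0.05, 0.5), landrace
frequencies Beta-distributed around them with differentiation `fst`
(default 0.15). LD is blocky: chromosomes are partitioned by a first-order
Markov process (a new block starts at each SNP with probability
`1 − exp(−d/L)`, mean block length `L` = 200 kb); each block shares one
frequency draw and, per line, one latent uniform that every SNP copies
except with probability 0.1 (so within-block r² ≈ 0.8, cross-block LD near
zero, and decay follows `exp(−d/L)`). Lines are homozygous everywhere —
dosage 0 or 2, never 1, matching an inbred panel.

**Designs.** The population-structure arm is the full factorial donors ×
(genotypes + blank) × replicates (12 × 25 × 3 = 900). The p-rep GWAS arm
replicates a chosen subset 7× and the rest 3× (36·7 + 263·3 = 1041
non-blank wells per donor at full panel size), randomizes wells on 8 × 12
plates under a seeded RNG, and groups consecutive plates into digestion
batches. Blanks per plate are a parameter because the source material's
totals do not pin the count down.

**Responses.** Latent per-taxon log2 abundances sum a long-tailed
(log-normal) donor baseline, landrace and market-class shifts, planted
allelic effects, Gaussian batch/plate/row/column effects and residual
noise; closure and multinomial sampling at the sequencing depth yield
counts, and SCFA traits are linear combinations of two producer taxa's
latent abundances plus noise. Blank wells receive the baseline community
only. Planted loci must segregate within both landraces (within-landrace
MAF ≥ 0.05): an effect fully confounded with structure is absorbed by the
structure covariates of the scan and is not what a recovery test should
plant.

**What passing tests do and do not show.** The simulator reproduces the
statistical skeleton the methods assume — population structure, blocky LD,
nuisance strata, compositional counts, planted pleiotropy — but not real
data's features: no sequencing error or chimeras, no taxon-taxon ecological
interactions, no donor-by-genotype interaction beyond the planted effects,
Gaussian nuisance effects, and LD blocks that are cleaner than recombination
makes them. Recovery on these conditions validates the implementation, not
the biology of any particular panel.

## Numerical choices and degenerate inputs

- Eigenvector signs: largest-magnitude entry positive, everywhere.
- CDA ridge: ε = 1e-8 relative to `trace(E)/p`, escalated ×100 only while
  the Cholesky remains ill-conditioned; always logged.
- Kinship Cholesky jitter: 1e-8 of the mean diagonal.
- Variance floors: 1e-10 of the trait variance; EM convergence 1e-6
  relative, 500 iterations.
- Constant traits: Kruskal–Wallis returns p = 1 with a warning; Spearman
  returns NA with a warning; the scan flags untestable SNPs rather than
  erroring.
- Saturated MANOVA designs (no residual df) and single-level factors: the
  former errors, the latter contribute a zero SSCP with zero df.
- Bin and interval conventions: association bins are 0-based half-open;
  internal MEL coordinates are 1-based inclusive bp; BED export shifts to
  0-based half-open.

## Problem sizes used by the test and acceptance suites

Chosen as desk-scale study conditions: heritability recovery uses 200
lines × 3 replicates × 50 seeds at σ²_g = σ²_e; MEL recovery uses 20 seeds
of a 200-line, 1,500-SNP, 11-chromosome genome (5 Mb chromosomes, so SNP
spacing ≪ LD block length, as in dense real maps) with two planted loci
each driving 6 taxa in 2 donors at 2 log2 units, plus 20 unplanted seeds
for the null; the type-I suite uses 50 null traits over 2,000-SNP panels.
The end-to-end pipeline fixture is 60 lines, 500 SNPs, 12 taxa, 2 donors.

## Known limitations

- The conditioned scan is a specified simplification of published
  iterative multi-locus methods; it does not reproduce any particular
  tool's internals (no random-model p-value unification, no SUPER-style
  bin optimization).
- MEL boundary calling at a hard r² = 0.75 cutoff fragments when realized
  LD hovers near the threshold: a strong locus can yield satellite regions
  from partially linked neighbors, so recovery is asserted as containment
  of the planted SNP plus locality, not as an exact region count — mirroring
  how adjacent loci on one chromosome appear as separate regions in real
  analyses.
- The mixed model is single-trait; multivariate mixed models and spatial
  field models are out of scope.
- `Σ_G` estimation error tracks the realized genotypic sample covariance;
  with few genotypes the difference-of-mean-squares estimator is noisy and
  can be indefinite.
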