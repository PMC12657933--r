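# melscan

Microbiome-trait GWAS and multiple-effect-locus (MEL) detection for
structured crop diversity panels.

## The problem

Genetic variation in food crops shapes how the human gut microbiome
ferments them — an interspecific indirect genetic effect. When seed from an
inbred diversity panel (here modeled on a 299-line common-bean panel
spanning the Durango and Mesoamerica landraces and six market classes) is
digested and fermented in vitro by fecal microbiomes, the resulting taxa
abundances, diversity metrics and short-chain fatty acid concentrations
become quantitative phenotypes of the plant genotype. `melscan` implements
the full computational chain from count tables to mapped loci, for
researchers doing microbiome-aware crop genetics:

- **Trait processing** — rarefaction, prevalence (10%) and mean
  relative-abundance (0.15%) filters applied per donor, log2 and centered
  log-ratio (CLR) transforms, alpha diversity (Shannon, Simpson, Pielou,
  observed, bias-corrected Chao1), taxonomy aggregation.
- **Community statistics** — Bray-Curtis distances, distance from blank
  controls, PERMANOVA (seeded permutations, `p = (1 + #{F* ≥ F})/(1 + N)`),
  Kruskal-Wallis with Benjamini-Hochberg adjustment, Dunn's post hoc,
  Spearman correlation, principal coordinates.
- **Polymicrobial traits** — sequential MANOVA SSCP decomposition
  (genotype, batch, plate(batch)) of the CLR-transformed core genera;
  hypothesis and genetic covariance/correlation matrices, the latter solved
  from expected mean squares, `Σ_G = (M_H − M_E)/c`; PCA of all four
  matrices and canonical discriminant analysis (`H a = λ E a`), giving 24
  score variables (16 PCA + 8 CDA).
- **Mixed model** — EM-REML variance components with a kinship-structured
  genotype effect and batch/plate/row/column nuisance effects; BLUPs;
  broad-sense heritability `H² = σ²_g / σ²_total` with the `H² ≥ 0.1`
  inclusion filter.
- **Association and MEL** — Bonferroni-controlled single-marker scan of
  BLUPs on five genotype PCs, an iterated pseudo-QTN conditioned scan,
  0.1 Mb association binning, and MEL calling: bins hit by ≥ 5 traits from
  ≥ 2 donor microbiomes, boundaries grown through LD `r² ≥ 0.75` regardless
  of distance.
- **Synthetic data** — genotype panels with Balding-Nichols structure and
  blocky LD, partially replicated (p-rep) fermentation designs, multinomial
  count and SCFA responses with planted pleiotropic loci, and allele-based
  line pooling — so every stage is testable by parameter recovery.

## Worked example

Simulate a structured panel with two planted pleiotropic loci, phenotype it
in two donor microbiomes, scan, and call MELs:

```r
library(melscan)

panel <- simulate_genotype_panel(
  n_lines_per_landrace = c(Durango = 120, Mesoamerica = 80),
  n_snps = 1500, ld_block_length = 2e5, chrom_length_bp = 5e6, seed = 1)
donors <- c("S768", "S770")
loci <- effect_loci_spec(panel, donors, n_loci = 2, n_taxa_affected = 6,
                         n_taxa = 20, effect_size = 2, seed = 1)
design <- simulate_fermentation_design("mdp_gwas", donors = donors,
  genotypes = panel$line_info$line_id, n_high = 20, seed = 1)
sim <- simulate_trait_responses(panel, design, loci = loci, n_taxa = 20,
                                depth = 2000, seed = 1)

pf  <- maf_filter(panel)           # MAF > 0.05: 1401 of 1500 SNPs remain
pcs <- genotype_pca(pf, 5)
lt  <- log2_abundance(sim$counts)

assoc <- do.call(rbind, lapply(donors, function(d) {
  rows <- sim$design$donor_id == d & sim$design$line_id != "BLANK"
  ym <- apply(lt[rows, ], 2, function(v) tapply(v, sim$design$line_id[rows], mean))
  do.call(rbind, lapply(colnames(ym), function(tr) {
    tab <- single_marker_scan(ym[, tr], pf, pcs)
    tab$donor <- d; tab$trait <- tr; tab
  }))
}))
mel <- call_mel(bin_associations(assoc), assoc, pf)
mel[, c("mel_id", "chrom", "start", "end", "n_traits", "n_donors")]
```

This prints (the planted loci were at `Pv09:1515957` and `Pv04:3854586`):

```
  mel_id chrom   start     end n_traits n_donors
1  MEL-A  Pv04 3644734 3873885       34        2
2  MEL-B  Pv09 1473256 1654096       13        2
```

Both planted loci are recovered as MEL regions containing the planted SNP:
`n_traits` counts the distinct (donor, trait) pairs with a significant SNP
in the region, `n_donors` the distinct microbiomes, and the interval spans
the LD-defined boundary set (`r² ≥ 0.75` to a seed SNP). `start`/`end` are
1-based bp; `write_mel_bed()` exports 0-based half-open BED with a JSON
sidecar of member SNPs and contributing traits.

The same chain runs end-to-end, including the mixed-model BLUP and
heritability-filter stages, via `run_pipeline(default_config(seed = 1),
out_dir)`, which writes every stage's tables plus a run manifest.

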