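# Small deterministic fixtures shared across test files.

# desk-scale structured panel
small_panel <- function(seed = 1, n_snps = 300, durango = 30, meso = 20, ...) {
  simulate_genotype_panel(
    n_lines_per_landrace = c(Durango = durango, Mesoamerica = meso),
    n_snps = n_snps, seed = seed, ...)
}

# balanced one-way multivariate toy with known genotypic structure
toy_sscp_data <- function() {
  # one variable, genotypes {1,3} and {5,7}: H = [[16]], E = [[4]]
  list(y = matrix(c(1, 3, 5, 7), ncol = 1), genotype = c("a", "a", "b", "b"))
}

# run panel -> responses -> line-mean traits -> marginal scan -> MEL calling
# for one seed; the planted truth travels with the result
mel_recovery_run <- function(seed, plant = TRUE, scan = "marginal") {
  panel <- simulate_genotype_panel(
    n_lines_per_landrace = c(Durango = 120, Mesoamerica = 80),
    n_snps = 1500, ld_block_length = 2e5, chrom_length_bp = 5e6, seed = seed)
  donors <- c("S768", "S770")
  loci <- if (plant) {
    effect_loci_spec(panel, donors, n_loci = 2, n_taxa_affected = 6,
                     n_taxa = 20, effect_size = 2, seed = seed)
  }
  design <- simulate_fermentation_design(
    "mdp_gwas", donors = donors, genotypes = panel$line_info$line_id,
    n_high = 20, seed = seed)
  sim <- simulate_trait_responses(panel, design, loci = loci, n_taxa = 20,
                                  depth = 2000, seed = seed)
  pf <- maf_filter(panel)
  pcs <- genotype_pca(pf, 5)
  lt <- log2_abundance(sim$counts)
  assoc <- list()
  for (d in donors) {
    rows <- sim$design$donor_id == d & sim$design$line_id != "BLANK"
    ym <- apply(lt[rows, , drop = FALSE], 2,
                function(v) tapply(v, sim$design$line_id[rows], mean))
    for (tr in colnames(ym)) {
      tab <- if (scan == "conditioned") {
        conditioned_scan(ym[, tr], pf, pcs)
      } else {
        single_marker_scan(ym[, tr], pf, pcs)
      }
      tab$donor <- d
      tab$trait <- tr
      assoc[[paste(d, tr)]] <- tab
    }
  }
  assoc <- do.call(rbind, assoc)
  mel <- call_mel(bin_associations(assoc), assoc, pf)
  list(panel = pf, loci = loci, assoc = assoc, mel = mel)
}

# TRUE iff every planted focal SNP is a member of some called MEL
planted_contained <- function(run) {
  planted <- vapply(run$loci, `[[`, "", "snp_id")
  all(vapply(planted, function(ps) {
    any(vapply(run$mel$member_snps, function(m) ps %in% m, logical(1)))
  }, logical(1)))
}
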