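#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: rarefaction depth
#' 7197, 10 percent prevalence and 0.15 percent mean-relative-abundance
#' trait filters, 90 percent core-genus coverage, MAF > 0.05, three genotype
#' PCs in the BLUP model and five in the scan, H2 >= 0.1 trait inclusion,
#' Bonferroni alpha 0.05, 0.1 Mb association bins, MEL qualification at 5
#' traits from 2 donors with LD r^2 >= 0.75 boundaries. Simulation sizes
#' default to a small desk-scale problem; override any entry via
#' \code{config}.
#'
#' @param ... named overrides of the defaults.
#' @return named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulation
    n_lines_per_landrace = c(Durango = 40, Mesoamerica = 20),
    n_snps = 500L, fst = 0.2, ld_block_length = 2e5, n_chrom = 11L,
    chrom_length_bp = 5e6,
    donors = c("S768", "S770"), n_taxa = 12L, n_loci = 1L,
    n_taxa_affected = 6L, effect_size = 2, depth = 2000L,
    # trait processing
    rarefy_depth = NULL, min_prevalence = 0.10, min_mean_relab = 0.0015,
    core_threshold = 0.90,
    # genetics / mixed model
    min_maf = 0.05, n_pcs_blup = 3L, n_pcs_scan = 5L, h2_threshold = 0.1,
    # association / MEL
    alpha = 0.05, scan = "marginal", bin_bp = 1e5, min_traits = 5L,
    min_donors = 2L, r2_threshold = 0.75, search_window_bp = 5e6
  )
  modifyList(cfg, list(...))
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> trait processing -> polymicrobial scores -> variance
#' components and heritability filter -> association scan -> MEL calling,
#' writing every stage's tables plus a run manifest to \code{out_dir}. All
#' randomness flows from \code{config$seed} through named per-stage
#' substreams, so the same configuration reproduces every output.
#'
#' @param config parameter list from \code{\link{default_config}}.
#' @param out_dir output directory (created if needed); existing manifests
#'   are only overwritten when \code{force = TRUE}.
#' @param force overwrite an existing run directory.
#' @return invisibly, a list with the panel, per-donor traits, BLUPs,
#'   heritabilities, the stacked association table and the MEL table.
#' @export
run_pipeline <- function(config = default_config(), out_dir, force = FALSE) {
  if (file.exists(file.path(out_dir, "manifest.json")) && !force) {
    stop("output directory already contains a run; use force = TRUE to overwrite")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate ---
  panel <- simulate_genotype_panel(
    n_lines_per_landrace = config$n_lines_per_landrace, n_snps = config$n_snps,
    fst = config$fst, ld_block_length = config$ld_block_length,
    n_chrom = config$n_chrom, chrom_length_bp = config$chrom_length_bp,
    seed = derive_seed(config$seed, "panel"))
  loci <- if (config$n_loci > 0) {
    effect_loci_spec(panel, donors = config$donors, n_loci = config$n_loci,
                     n_taxa_affected = config$n_taxa_affected,
                     n_taxa = config$n_taxa, effect_size = config$effect_size,
                     seed = derive_seed(config$seed, "loci"))
  }
  design <- simulate_fermentation_design(
    arm = "mdp_gwas", donors = config$donors,
    genotypes = panel$line_info$line_id,
    n_high = max(1L, nrow(panel$line_info) %/% 8L),
    seed = derive_seed(config$seed, "design"))
  sim <- simulate_trait_responses(
    panel, design, loci = loci, n_taxa = config$n_taxa, depth = config$depth,
    seed = derive_seed(config$seed, "responses"))
  write_genotypes_tsv(panel, file.path(out_dir, "genotypes.tsv"),
                      file.path(out_dir, "snp_map.tsv"))
  write_table_tsv(sim$counts, file.path(out_dir, "counts.tsv"))
  write_table_tsv(sim$scfa, file.path(out_dir, "scfa.tsv"))
  write.table(design, file.path(out_dir, "design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(loci)) {
    jsonlite::write_json(
      lapply(loci, function(l) l[c("snp_id", "chrom", "pos", "taxa", "donors")]),
      file.path(out_dir, "planted_loci.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- genetics-side inputs ---
  panel_f <- maf_filter(panel, config$min_maf)
  pcs_all <- genotype_pca(panel_f, k = max(config$n_pcs_blup, config$n_pcs_scan))
  kin <- centered_kinship(panel_f)

  # --- per-donor trait processing, BLUPs, scan ---
  counts <- sim$counts
  if (!is.null(config$rarefy_depth)) {
    counts <- rarefy(counts, config$rarefy_depth,
                     seed = derive_seed(config$seed, "rarefy"))
  }
  assoc_all <- list(); h2_all <- list(); blup_all <- list()
  for (d in config$donors) {
    rows <- design$donor_id == d & design$line_id != "BLANK"
    cts <- filter_taxa(counts[design$sample_id[rows], , drop = FALSE],
                       config$min_prevalence, config$min_mean_relab)
    traits <- log2_abundance(cts)
    shannon <- alpha_diversity_table(cts, metrics = "shannon")
    scfa <- sim$scfa[design$sample_id[rows], , drop = FALSE]
    core <- select_core_genera(cts, config$core_threshold)
    sub_design <- design[rows, , drop = FALSE]
    poly <- if (length(core) >= 4) {
      ps <- polymicrobial_scores(clr_transform(cts[, core, drop = FALSE]),
                                 genotype = sub_design$line_id,
                                 batch = sub_design$digestion_batch,
                                 plate = sub_design$plate_id)
      ps$scores
    }
    trait_mat <- cbind(traits, shannon, scfa, poly)
    write_table_tsv(trait_mat, file.path(out_dir, paste0("traits_", d, ".tsv")))

    pcs_blup <- pcs_all[, seq_len(config$n_pcs_blup), drop = FALSE]
    h2 <- numeric(0); blups <- list()
    for (tr in colnames(trait_mat)) {
      fit <- tryCatch(
        suppressWarnings(fit_variance_components(
          trait_mat[, tr], sub_design, K = kin, pcs = pcs_blup)),
        error = function(e) NULL)
      if (is.null(fit)) next
      h2[tr] <- broad_sense_h2(fit)
      blups[[tr]] <- fit$blup
    }
    h2_all[[d]] <- h2
    blup_all[[d]] <- blups
    retained <- suppressMessages(
      heritability_filter(h2, threshold = config$h2_threshold))
    pcs_scan <- pcs_all[, seq_len(config$n_pcs_scan), drop = FALSE]
    for (tr in retained) {
      tab <- if (identical(config$scan, "conditioned")) {
        conditioned_scan(blups[[tr]], panel_f, pcs_scan, alpha = config$alpha)
      } else {
        single_marker_scan(blups[[tr]], panel_f, pcs_scan, alpha = config$alpha)
      }
      tab$donor <- d; tab$trait <- tr
      assoc_all[[paste(d, tr)]] <- tab
    }
  }
  assoc <- do.call(rbind, assoc_all)
  rownames(assoc) <- NULL
  write.table(assoc, file.path(out_dir, "associations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- MEL ---
  bins <- bin_associations(assoc, config$bin_bp)
  mel <- call_mel(bins, assoc, panel_f, min_traits = config$min_traits,
                  min_donors = config$min_donors,
                  r2_threshold = config$r2_threshold,
                  search_window_bp = config$search_window_bp)
  if (nrow(mel)) write_mel_bed(mel, file.path(out_dir, "mel.bed"))

  manifest <- list(
    package = "melscan",
    version = as.character(utils::packageVersion("melscan")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[setdiff(names(config), "seed")],
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, loci = loci, h2 = h2_all, blups = blup_all,
                 associations = assoc, bins = bins, mel = mel))
}
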