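# realistic genus labels for simulated communities (dominant fecal genera,
# long tail padded with numbered placeholders)
default_taxa_names <- function(n) {
  base <- c("Bacteroides", "Prevotella", "Faecalibacterium", "Blautia",
            "Anaerostipes", "Coprococcus", "Dorea", "Roseburia",
            "Fusicatenibacter", "Lachnoclostridium", "Ruminococcus",
            "Bifidobacterium", "Sutterella", "Phascolarctobacterium",
            "Agathobacter", "Subdoligranulum", "Dialister", "Alistipes",
            "Parabacteroides", "Akkermansia", "Succinivibrio", "Lachnospira",
            "Eubacterium_hallii_group", "Ruminococcaceae_UCG002")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("Taxon%02d", seq_len(n - length(base))))
}

#' Specify planted pleiotropic effect loci
#'
#' Chooses focal SNPs and the taxa/donors they affect, recording the planted
#' truth used by parameter-recovery tests of the association scan and MEL
#' caller. Each locus shifts the latent log2 abundance of its affected taxa
#' by \code{effect_size} units between dosage-0 and dosage-2 lines.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param donors donor ids the effects act in.
#' @param n_loci number of planted loci; focal SNPs are drawn from distinct
#'   chromosomes where possible.
#' @param n_taxa_affected taxa affected per locus.
#' @param n_taxa total taxa in the simulated community (affected taxa are
#'   sampled from these indices).
#' @param effect_size per-locus effect in log2 units (dosage 2 vs dosage 0);
#'   signs alternate across affected taxa.
#' @param min_maf minimum minor allele frequency a focal SNP must have.
#' @param min_within_landrace_maf minimum minor allele frequency within each
#'   landrace. Planted loci must segregate inside the landraces: effects
#'   fully confounded with population structure are (by design) absorbed by
#'   the structure covariates of the association model and are not what a
#'   recovery test should plant.
#' @param seed integer seed.
#'
#' @return An object of class \code{effect_loci_spec}: a list with one
#'   element per locus (\code{snp_id}, \code{snp_index}, \code{chrom},
#'   \code{pos}, \code{taxa} indices, \code{donors}, \code{effects} matrix
#'   donors x taxa in log2 units).
#' @export
effect_loci_spec <- function(panel, donors, n_loci = 2L, n_taxa_affected = 6L,
                             n_taxa = 30L, effect_size = 1.5, min_maf = 0.15,
                             min_within_landrace_maf = 0.05, seed = 1L) {
  maf <- minor_allele_freq(panel)
  eligible <- maf >= min_maf & maf <= 0.5
  for (lr in unique(panel$line_info$landrace)) {
    g_lr <- panel$genotypes[panel$line_info$landrace == lr, , drop = FALSE]
    f_lr <- colMeans(g_lr, na.rm = TRUE) / 2
    f_lr <- pmin(f_lr, 1 - f_lr)
    eligible <- eligible & !is.na(f_lr) & f_lr >= min_within_landrace_maf
  }
  eligible <- which(eligible)
  if (length(eligible) < n_loci) stop("not enough SNPs at the requested minimum MAF")
  with_seed(seed, {
    # prefer distinct chromosomes so loci are unlinked
    chroms <- panel$snp_map$chrom[eligible]
    picked <- integer(0)
    for (ch in sample(unique(chroms))) {
      if (length(picked) >= n_loci) break
      picked <- c(picked, sample(eligible[chroms == ch], 1))
    }
    while (length(picked) < n_loci) {
      picked <- c(picked, sample(setdiff(eligible, picked), 1))
    }
    loci <- lapply(picked, function(j) {
      taxa <- sample.int(n_taxa, n_taxa_affected)
      eff <- matrix(effect_size * rep_len(c(1, -1), n_taxa_affected),
                    nrow = length(donors), ncol = n_taxa_affected, byrow = TRUE,
                    dimnames = list(donors, NULL))
      list(snp_id = panel$snp_map$snp_id[j], snp_index = j,
           chrom = panel$snp_map$chrom[j], pos = panel$snp_map$pos[j],
           taxa = taxa, donors = donors, effects = eff)
    })
    structure(loci, class = "effect_loci_spec")
  })
}

#' Simulate microbiome and metabolite responses for a fermentation design
#'
#' Generates per-well taxa counts and short-chain fatty acid (SCFA) traits
#' with the variance structure the downstream analysis assumes. For each
#' sample, the latent log2 abundance of each taxon is
#' donor baseline + landrace/market-class shift + planted allelic effects +
#' digestion-batch + plate + row + column effects + residual noise; relative
#' abundances follow by exponentiation and closure, and counts are drawn
#' multinomially at the sequencing depth. SCFA traits are linear
#' combinations of producer-taxon latent abundances plus noise. Blank wells
#' carry the donor baseline community only (no substrate, structure or
#' locus effects).
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param design a design data.frame from
#'   \code{\link{simulate_fermentation_design}}.
#' @param loci optional \code{\link{effect_loci_spec}} of planted loci.
#' @param n_taxa number of taxa in each donor community.
#' @param baseline_sd spread (log2 units) of donor baseline abundances; the
#'   baselines are log-normal, giving a long-tailed community.
#' @param structure_sd sd of per-(taxon, landrace) and per-(taxon, market
#'   class) shifts emulating population-structure effects (0 disables).
#' @param noise named list of standard deviations for the nuisance strata
#'   \code{batch}, \code{plate}, \code{row}, \code{column} (per taxon-level
#'   draws) and \code{residual} (per observation).
#' @param depth multinomial sequencing depth per sample.
#' @param n_scfa number of SCFA traits (named from acetate, propionate,
#'   butyrate, ...); each is driven by two producer taxa.
#' @param scfa_noise_sd residual sd of the SCFA traits.
#' @param seed integer seed.
#'
#' @return list with \code{counts} (samples x taxa integer matrix),
#'   \code{scfa} (samples x SCFA matrix), \code{latent} (samples x taxa
#'   latent log2 abundances), \code{design}, and \code{truth} (donor
#'   baseline proportions, planted loci, structure shifts, SCFA producer
#'   map).
#' @export
simulate_trait_responses <- function(panel, design, loci = NULL,
                                     n_taxa = 30L,
                                     baseline_sd = 2,
                                     structure_sd = 0.3,
                                     noise = list(batch = 0.2, plate = 0.15,
                                                  row = 0.1, column = 0.1,
                                                  residual = 0.3),
                                     depth = 7197L,
                                     n_scfa = 3L,
                                     scfa_noise_sd = 0.3,
                                     seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  non_blank <- design$line_id[design$line_id != "BLANK"]
  unknown <- setdiff(non_blank, panel$line_info$line_id)
  if (length(unknown)) stop("design lines missing from panel: ",
                            paste(head(unknown, 5), collapse = ", "))
  taxa <- default_taxa_names(n_taxa)
  donors <- unique(design$donor_id)
  scfa_names <- c("acetate", "propionate", "butyrate", "iso_butyrate",
                  "iso_valerate", "valerate")[seq_len(n_scfa)]

  with_seed(seed, {
    # donor baseline communities: log-normal abundances -> log2 baselines
    baseline <- matrix(log2(rlnorm(length(donors) * n_taxa, 0, baseline_sd * log(2))),
                       length(donors), n_taxa, dimnames = list(donors, taxa))

    landraces <- unique(panel$line_info$landrace)
    classes <- unique(panel$line_info$market_class)
    land_shift <- matrix(rnorm(length(landraces) * n_taxa, 0, structure_sd),
                         length(landraces), n_taxa, dimnames = list(landraces, taxa))
    class_shift <- matrix(rnorm(length(classes) * n_taxa, 0, structure_sd / 2),
                          length(classes), n_taxa, dimnames = list(classes, taxa))

    # nuisance effects per (stratum level, taxon)
    stratum_effects <- function(levels, sd) {
      matrix(rnorm(length(levels) * n_taxa, 0, sd), length(levels), n_taxa,
             dimnames = list(levels, taxa))
    }
    eff_batch <- stratum_effects(unique(design$digestion_batch), noise$batch %||% 0)
    eff_plate <- stratum_effects(unique(design$plate_id), noise$plate %||% 0)
    row_key <- paste(design$plate_id, design$plate_row)
    col_key <- paste(design$plate_id, design$plate_column)
    eff_row <- stratum_effects(unique(row_key), noise$row %||% 0)
    eff_col <- stratum_effects(unique(col_key), noise$column %||% 0)

    n <- nrow(design)
    z <- baseline[design$donor_id, , drop = FALSE]
    is_blank <- design$line_id == "BLANK"
    line_row <- match(design$line_id, panel$line_info$line_id)

    if (structure_sd > 0 && any(!is_blank)) {
      lr <- panel$line_info$landrace[line_row]
      mc <- panel$line_info$market_class[line_row]
      z[!is_blank, ] <- z[!is_blank, , drop = FALSE] +
        land_shift[lr[!is_blank], , drop = FALSE] +
        class_shift[mc[!is_blank], , drop = FALSE]
    }
    if (!is.null(loci)) {
      for (lc in loci) {
        dose <- panel$genotypes[line_row, lc$snp_index]
        dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
        for (d in lc$donors) {
          sel <- !is_blank & design$donor_id == d
          if (!any(sel)) next
          z[sel, lc$taxa] <- z[sel, lc$taxa, drop = FALSE] +
            outer(dose[sel] / 2, lc$effects[d, ])
        }
      }
    }
    z <- z + eff_batch[design$digestion_batch, , drop = FALSE] +
      eff_plate[design$plate_id, , drop = FALSE] +
      eff_row[row_key, , drop = FALSE] +
      eff_col[col_key, , drop = FALSE] +
      matrix(rnorm(n * n_taxa, 0, noise$residual %||% 0), n, n_taxa)
    dimnames(z) <- list(design$sample_id, taxa)

    rel <- 2^z
    rel <- rel / rowSums(rel)
    counts <- t(apply(rel, 1, function(p) rmultinom(1, depth, p)[, 1]))
    dimnames(counts) <- dimnames(z)

    # SCFA driven by producer taxa (two per metabolite, coefficient 0.5 on
    # latent log2 abundance)
    producers <- lapply(seq_len(n_scfa), function(k) {
      idx <- ((k - 1L) * 2L) %% n_taxa + c(1L, 2L)
      setNames(c(0.5, 0.5), taxa[idx])
    })
    names(producers) <- scfa_names
    scfa <- sapply(producers, function(w) {
      z[, names(w), drop = FALSE] %*% w + rnorm(n, 0, scfa_noise_sd)
    })
    dimnames(scfa) <- list(design$sample_id, scfa_names)

    base_prop <- 2^baseline
    base_prop <- base_prop / rowSums(base_prop)
    list(counts = counts, scfa = scfa, latent = z, design = design,
         truth = list(baseline_proportions = base_prop, loci = loci,
                      landrace_shift = land_shift, class_shift = class_shift,
                      scfa_producers = producers))
  })
}

#' Pool lines by genotype class at a focal SNP
#'
#' Emulates the bean-flour pooling used to validate allelic effects: within
#' each market class, lines homozygous for the major allele form one pool and
#' lines homozygous for the minor allele another. A pooled pseudo-sample's
#' latent trait is the equal-weight mean of its member lines' traits. Market
#' classes lacking lines in either genotype class are skipped with a warning.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param focal_snp SNP id (must be polymorphic in the panel).
#' @param traits optional numeric matrix of line-level trait values (rows
#'   named by line id); pooled means are returned when supplied.
#' @return data.frame of pools (\code{pool_id}, \code{market_class},
#'   \code{allele_class}, \code{n_lines}, \code{lines} as a list column) with
#'   attribute \code{"pooled_traits"} (pools x traits matrix) when
#'   \code{traits} is given.
#' @export
pool_lines_by_allele <- function(panel, focal_snp, traits = NULL) {
  j <- match(focal_snp, panel$snp_map$snp_id)
  if (is.na(j)) stop("focal SNP not found: ", focal_snp)
  dose <- panel$genotypes[, j]
  if (length(unique(dose[!is.na(dose)])) < 2) {
    stop("focal SNP is monomorphic across the panel")
  }
  if (!is.null(traits)) {
    traits <- as.matrix(traits)
    if (is.null(rownames(traits))) stop("traits must have line ids as rownames")
  }
  pools <- list()
  pooled <- list()
  for (mc in unique(panel$line_info$market_class)) {
    for (cls in c("major", "minor")) {
      want <- if (cls == "major") 0 else 2
      members <- panel$line_info$line_id[panel$line_info$market_class == mc &
                                           !is.na(dose) & dose == want]
      if (length(members) == 0) {
        if (cls == "minor") {
          warning(sprintf("no %s-allele lines in market class '%s'; pool skipped",
                          cls, mc), call. = FALSE)
        }
        next
      }
      pid <- paste(mc, cls, sep = "_")
      pools[[pid]] <- data.frame(pool_id = pid, market_class = mc,
                                 allele_class = cls, n_lines = length(members),
                                 stringsAsFactors = FALSE)
      pools[[pid]]$lines <- list(members)
      if (!is.null(traits)) {
        pooled[[pid]] <- colMeans(traits[members, , drop = FALSE])
      }
    }
  }
  out <- do.call(rbind, pools)
  rownames(out) <- NULL
  if (!is.null(traits)) {
    attr(out, "pooled_traits") <- do.call(rbind, pooled)
  }
  out
}
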