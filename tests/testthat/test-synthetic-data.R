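test_that("panel simulation is deterministic and respects the inbred contract", {
  p1 <- small_panel(seed = 11)
  p2 <- small_panel(seed = 11)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$snp_map, p2$snp_map)
  p3 <- small_panel(seed = 12)
  expect_false(identical(p1$genotypes, p3$genotypes))

  expect_true(all(p1$genotypes %in% c(0, 2)))
  for (ch in unique(p1$snp_map$chrom)) {
    expect_true(all(diff(p1$snp_map$pos[p1$snp_map$chrom == ch]) > 0))
  }
  # market classes nest within landraces
  tab <- unique(p1$line_info[, c("landrace", "market_class")])
  expect_equal(anyDuplicated(tab$market_class), 0L)
})

test_that("default panel matches the 299-line two-landrace composition", {
  p <- simulate_genotype_panel(n_snps = 50, seed = 1)
  expect_equal(nrow(p$genotypes), 299)
  expect_equal(as.vector(table(p$line_info$landrace)[c("Durango", "Mesoamerica")]),
               c(198, 101))
  expect_equal(length(unique(p$line_info$market_class)), 6)
})

test_that("landrace allele-frequency differentiation vanishes as fst -> 0", {
  diffs <- vapply(1:10, function(s) {
    p <- simulate_genotype_panel(c(Durango = 150, Mesoamerica = 150),
                                 n_snps = 200, fst = 0.002, seed = s)
    f <- sapply(split(seq_len(300), p$line_info$landrace), function(idx) {
      colMeans(p$genotypes[idx, , drop = FALSE]) / 2
    })
    mean(f[, 1] - f[, 2])
  }, numeric(1))
  # Monte-Carlo error of the mean frequency difference at fst ~ 0
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.01)
})

test_that("panel simulation rejects invalid parameters", {
  expect_error(simulate_genotype_panel(c(Durango = 0, Mesoamerica = 10), n_snps = 10),
               "positive")
  expect_error(small_panel(fst = 1.2), "fst")
  expect_error(small_panel(n_snps = 0), "n_snps")
})

test_that("population-structure design arm yields the full factorial", {
  d <- simulate_fermentation_design(
    "population_structure", donors = paste0("D", 1:12),
    genotypes = paste0("G", 1:24), replicates = 3, seed = 5)
  expect_equal(nrow(d), 900) # 12 x (24 + 1 blank) x 3
  expect_equal(sum(d$line_id == "BLANK"), 12 * 3)
  # wells unique within plate
  expect_equal(anyDuplicated(paste(d$plate_id, d$plate_row, d$plate_column)), 0L)
})

test_that("p-rep arm replicates 36 lines 7x and the rest 3x", {
  d <- simulate_fermentation_design(
    "mdp_gwas", donors = "S768", genotypes = sprintf("L%03d", 1:299),
    n_high = 36, seed = 2)
  nb <- d[d$line_id != "BLANK", ]
  expect_equal(nrow(nb), 36 * 7 + 263 * 3) # 1041
  reps <- table(nb$line_id)
  expect_equal(sort(unique(as.vector(reps))), c(3, 7))
  expect_equal(sum(reps == 7), 36)
  # every plate carries its blank wells
  expect_true(all(table(d$plate_id[d$line_id == "BLANK"]) == 1))
})

test_that("design generation errors on degenerate inputs", {
  expect_error(simulate_fermentation_design("mdp_gwas", donors = "d",
                                            genotypes = character(0)),
               "genotype")
  expect_error(simulate_fermentation_design("mdp_gwas", donors = "d",
                                            genotypes = paste0("g", 1:500),
                                            max_plates = 2),
               "capacity")
})

test_that("trait responses conserve depth and recover planted direction", {
  panel <- small_panel(seed = 3, durango = 120, meso = 80, n_snps = 200)
  donors <- "S768"
  loci <- effect_loci_spec(panel, donors, n_loci = 1, n_taxa_affected = 1,
                           n_taxa = 10, effect_size = 3, seed = 3)
  design <- simulate_fermentation_design(
    "mdp_gwas", donors = donors, genotypes = panel$line_info$line_id,
    n_high = 10, seed = 3)
  sim <- simulate_trait_responses(panel, design, loci = loci, n_taxa = 10,
                                  depth = 5000, seed = 3)
  expect_true(all(rowSums(sim$counts) == 5000))
  expect_true(all(sim$counts >= 0))
  # determinism
  sim2 <- simulate_trait_responses(panel, design, loci = loci, n_taxa = 10,
                                   depth = 5000, seed = 3)
  expect_identical(sim$counts, sim2$counts)

  # planted locus shifts its taxon in the planted direction (200 lines)
  lc <- loci[[1]]
  nb <- sim$design$line_id != "BLANK"
  dose <- panel$genotypes[match(sim$design$line_id[nb], panel$line_info$line_id),
                          lc$snp_index]
  z <- sim$latent[nb, lc$taxa[1]]
  gap <- mean(z[dose == 2]) - mean(z[dose == 0])
  expect_equal(unname(sign(gap)), unname(sign(lc$effects[donors, 1])))
  expect_gt(abs(gap), 1)
})

test_that("no-signal limit recovers donor baseline proportions", {
  panel <- small_panel(seed = 4, durango = 10, meso = 8, n_snps = 50)
  design <- simulate_fermentation_design(
    "population_structure", donors = "D1",
    genotypes = panel$line_info$line_id[1:5], replicates = 2, seed = 4)
  sim <- simulate_trait_responses(
    panel, design, loci = NULL, n_taxa = 8, structure_sd = 0,
    noise = list(batch = 0, plate = 0, row = 0, column = 0, residual = 0),
    depth = 2e5, seed = 4)
  rel <- sim$counts / rowSums(sim$counts)
  base <- sim$truth$baseline_proportions["D1", ]
  expect_lt(max(abs(sweep(rel, 2, base))), 0.005)
})

test_that("blank wells carry the baseline community only", {
  panel <- small_panel(seed = 5, durango = 10, meso = 8, n_snps = 50)
  design <- simulate_fermentation_design(
    "population_structure", donors = "D1",
    genotypes = panel$line_info$line_id[1:4], replicates = 2, seed = 5)
  sim <- simulate_trait_responses(
    panel, design, n_taxa = 6, structure_sd = 0.8,
    noise = list(batch = 0, plate = 0, row = 0, column = 0, residual = 0),
    depth = 1e5, seed = 5)
  blank <- sim$design$line_id == "BLANK"
  z_blank <- sim$latent[blank, , drop = FALSE]
  base <- log2(2^sim$truth$baseline_proportions) # proportions, not latent
  # blanks have identical latent rows (baseline only, no per-line effects)
  expect_lt(max(apply(z_blank, 2, function(col) diff(range(col)))), 1e-12)
})

test_that("allele pooling partitions lines and skips empty pools", {
  panel <- small_panel(seed = 6, durango = 40, meso = 30, n_snps = 100)
  maf <- minor_allele_freq(panel)
  snp <- panel$snp_map$snp_id[which(maf > 0.2 & maf < 0.5)[1]]
  traits <- matrix(rnorm(70 * 2), 70, 2,
                   dimnames = list(panel$line_info$line_id, c("t1", "t2")))
  pools <- suppressWarnings(pool_lines_by_allele(panel, snp, traits))
  # partition: every pooled line appears exactly once, in the right pool
  all_members <- unlist(pools$lines)
  expect_equal(anyDuplicated(all_members), 0L)
  dose <- panel$genotypes[, snp]
  for (i in seq_len(nrow(pools))) {
    mem <- pools$lines[[i]]
    expect_equal(length(mem), pools$n_lines[i])
    info <- panel$line_info[match(mem, panel$line_info$line_id), ]
    expect_true(all(info$market_class == pools$market_class[i]))
    want <- if (pools$allele_class[i] == "major") 0 else 2
    expect_true(all(dose[mem] == want))
  }
  # completeness: every homozygous line of a pooled (class, allele) is present
  pooled_keys <- paste(pools$market_class, pools$allele_class)
  info_all <- panel$line_info
  expect_cnt <- sum(paste(info_all$market_class,
                          ifelse(dose[info_all$line_id] == 0, "major", "minor"))
                    %in% pooled_keys, na.rm = TRUE)
  expect_equal(length(all_members), expect_cnt)
  # pooled trait = mean of members
  pt <- attr(pools, "pooled_traits")
  i <- 1
  expect_equal(unname(pt[pools$pool_id[i], ]),
               unname(colMeans(traits[pools$lines[[i]], , drop = FALSE])))
  # monomorphic focal SNP errors
  mono <- which(maf == 0)[1]
  if (!is.na(mono)) {
    expect_error(pool_lines_by_allele(panel, panel$snp_map$snp_id[mono]),
                 "monomorphic")
  }
  # a market class with no minor-allele line warns and is skipped
  rare <- panel$snp_map$snp_id[which(maf > 0 & maf < 0.03)[1]]
  if (!is.na(rare)) {
    w <- capture_warnings(pool_lines_by_allele(panel, rare))
    expect_true(any(grepl("skipped", w)))
  }
})
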