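# assemble a minimal association-table row
assoc_row <- function(donor, trait, snp_id, chrom, pos, sig = TRUE) {
  data.frame(donor = donor, trait = trait, snp_id = snp_id, chrom = chrom,
             pos = pos, effect = 1, se = 0.1, p = 1e-9, lod = 9,
             significant = sig, stringsAsFactors = FALSE)
}

test_that("0.1 Mb binning groups proximal SNPs and uses half-open bins", {
  # three SNPs within a 100-bp window land in one bin (index 96)
  a <- rbind(assoc_row("S770", "t1", "s1", "Pv05", 9615001),
             assoc_row("S770", "t2", "s2", "Pv05", 9615026),
             assoc_row("S776", "t3", "s3", "Pv05", 9614950))
  bins <- bin_associations(a, bin_bp = 1e5)
  expect_equal(nrow(bins), 1)
  expect_equal(bins$bin_index, 96L)
  expect_equal(bins$n_traits, 3L)
  expect_equal(bins$n_donors, 2L)
  # a SNP at an exact boundary goes to the upper bin
  b <- bin_associations(assoc_row("d", "t", "s", "Pv01", 2e5), bin_bp = 1e5)
  expect_equal(b$bin_index, 2L)
  # insignificant rows produce an empty summary
  empty <- bin_associations(assoc_row("d", "t", "s", "Pv01", 5, sig = FALSE))
  expect_equal(nrow(empty), 0)
})

test_that("MEL qualification needs enough traits from enough donors", {
  pos <- 9615000 + 1:5
  five_two <- do.call(rbind, lapply(1:5, function(i) {
    assoc_row(c("S770", "S776")[1 + i %% 2], paste0("t", i), paste0("s", i),
              "Pv05", pos[i])
  }))
  panel <- small_panel(seed = 51, n_snps = 100)
  # synthetic SNP ids do not exist in the panel map; build a matching panel
  g <- panel$genotypes[, 1:5]
  colnames(g) <- paste0("s", 1:5)
  map <- data.frame(snp_id = paste0("s", 1:5), chrom = "Pv05", pos = pos,
                    major = "A", minor = "G")
  p5 <- genotype_panel(g, map, panel$line_info)
  mel <- call_mel(bin_associations(five_two), five_two, p5)
  expect_equal(nrow(mel), 1)
  expect_equal(mel$n_donors, 2L)
  # same five traits from a single donor never qualify
  five_one <- five_two
  five_one$donor <- "S770"
  expect_equal(nrow(call_mel(bin_associations(five_one), five_one, p5)), 0)
  # stringent tier flags > 15 contributing pairs
  expect_false(mel$stringent)
})

test_that("LD expansion spans distant SNPs at r2 = 1 regardless of distance", {
  set.seed(52)
  base <- sample(c(0, 2), 80, replace = TRUE)
  g <- cbind(s1 = base, s2 = base, s3 = sample(c(0, 2), 80, replace = TRUE))
  rownames(g) <- sprintf("L%03d", 1:80)
  map <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "Pv02",
                    pos = c(1e6, 1.3e6, 2.6e6), major = "A", minor = "G")
  info <- data.frame(line_id = rownames(g), landrace = "D", market_class = "pinto")
  panel <- genotype_panel(g, map, info)
  a <- do.call(rbind, lapply(1:5, function(i) {
    assoc_row(c("d1", "d2")[1 + i %% 2], paste0("t", i), "s1", "Pv02", 1e6)
  }))
  mel <- call_mel(bin_associations(a), a, panel)
  expect_equal(nrow(mel), 1)
  # s2 at 300 kb with r2 = 1 joins the boundary set; s3 does not
  expect_setequal(mel$member_snps[[1]], c("s1", "s2"))
  expect_equal(mel$start, 1e6)
  expect_equal(mel$end, 1.3e6)
})

test_that("planted pleiotropic loci are recovered as MELs and nulls stay clean", {
  runs <- lapply(1:6, mel_recovery_run)
  contained <- vapply(runs, planted_contained, logical(1))
  expect_gte(mean(contained), 5 / 6)
  # every called region lies near a planted locus (locality / specificity)
  for (r in runs) {
    planted <- data.frame(chrom = vapply(r$loci, `[[`, "", "chrom"),
                          pos = vapply(r$loci, `[[`, 0, "pos"))
    for (i in seq_len(nrow(r$mel))) {
      near <- planted$chrom == r$mel$chrom[i] &
        planted$pos >= r$mel$start[i] - 5e6 & planted$pos <= r$mel$end[i] + 5e6
      expect_true(any(near))
    }
  }
  # null seeds produce no MELs
  null_mels <- vapply(1:4, function(s) {
    nrow(mel_recovery_run(s + 60, plant = FALSE)$mel)
  }, numeric(1))
  expect_equal(sum(null_mels), 0)
})

test_that("MEL provenance reconstructs its qualification counts", {
  run <- mel_recovery_run(1)
  for (i in seq_len(nrow(run$mel))) {
    pairs <- run$mel$pairs[[i]]
    expect_equal(run$mel$n_traits[i], length(unique(pairs)))
    expect_equal(run$mel$n_donors[i],
                 length(unique(sub("\\|.*$", "", pairs))))
    pos <- run$panel$snp_map$pos[match(run$mel$member_snps[[i]],
                                       run$panel$snp_map$snp_id)]
    expect_true(all(pos >= run$mel$start[i] & pos <= run$mel$end[i]))
  }
})

test_that("allelic effects summarize genotype classes with market-class detail", {
  g <- cbind(snp = c(0, 0, 2, 2, 2))
  rownames(g) <- paste0("L", 1:5)
  map <- data.frame(snp_id = "snp", chrom = "Pv05", pos = 9615026,
                    major = "A", minor = "G")
  info <- data.frame(line_id = rownames(g),
                     landrace = "D",
                     market_class = c("pinto", "pinto", "pinto", "pink", "pink"))
  panel <- genotype_panel(g, map, info)
  trait <- setNames(c(2, 4, 6, 8, 7), rownames(g))
  ae <- allelic_effects(trait, panel, "snp")
  expect_equal(ae$effect, mean(c(6, 8, 7)) - 3)
  expect_equal(ae$overall$n, c(2, 3))
  # a single-line class reports an undefined SD
  pinto_minor <- ae$by_market_class[
    ae$by_market_class$market_class == "pinto" &
      ae$by_market_class$class == "minor", ]
  expect_equal(pinto_minor$n, 1)
  expect_true(is.na(pinto_minor$sd))
  # identical class means give a zero effect
  t0 <- setNames(rep(1, 5), rownames(g))
  expect_equal(allelic_effects(t0, panel, "snp")$effect, 0)
  # hand value: major {2,4}, minor {6,8}
  t4 <- setNames(c(2, 4, 6, 8, NA), rownames(g))
  expect_equal(allelic_effects(t4[1:4], melscan:::subset_panel(panel, lines = 1:4),
                               "snp")$effect, 4)
})

test_that("log2 fold change follows the stated pseudocount form", {
  expect_equal(log2_fold_change(c(4, 4), c(1, 1), pseudo = 1e-9), 2,
               tolerance = 1e-6)
  expect_equal(log2_fold_change(0.5, 0.5), 0)
  expect_equal(log2_fold_change(0.03, 0.01, pseudo = 1e-6),
               log2(0.030001 / 0.010001))
  expect_equal(round(log2_fold_change(0.03, 0.01, pseudo = 1e-6), 3), 1.585)
  out <- log2_fold_change(0, 0)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "undefined"))
})

test_that("concordance counts sign agreement and ranks shared traits", {
  ref <- c(a = 1, b = 2, c = -1, d = -2)
  test <- c(a = 0.5, b = 1.5, c = -0.2, d = 0.7)
  out <- concordance(ref, test)
  expect_equal(out$agree, 3L)
  expect_equal(out$agreement, 0.75)
  # rank-Pearson by hand: ranks (3,4,2,1) vs (2,4,1,3) -> rho 0.4
  expect_equal(out$rho, cor(rank(ref), rank(test)))
  expect_equal(out$rho, 0.4)
  # perfect and inverted agreement
  expect_equal(concordance(ref, ref)$agreement, 1)
  expect_equal(concordance(ref, ref)$rho, 1)
  expect_equal(concordance(ref, -ref)$agreement, 0)
  expect_equal(concordance(ref, -ref)$rho, -1)
  expect_error(concordance(ref, c(x = 1, y = 2)), "shared")
})
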