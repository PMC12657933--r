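#' Genotype panel container
#'
#' Bundles an inbred-line biallelic genotype matrix with its SNP map and
#' population-structure labels. Lines are fully homozygous, so dosages take
#' values in \{0, 2\} (minor-allele copies), with \code{NA} for missing calls.
#'
#' @param genotypes numeric matrix, lines x SNPs, entries in \{0, 2, NA\};
#'   rownames are line ids, colnames SNP ids.
#' @param snp_map data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{major}, \code{minor}; positions must be
#'   strictly increasing within chromosome.
#' @param line_info data.frame with columns \code{line_id}, \code{landrace},
#'   \code{market_class}; market classes must nest within landraces.
#'
#' @return An object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(genotypes, snp_map, line_info) {
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(snp_map) == ncol(genotypes), nrow(line_info) == nrow(genotypes))
  bad <- genotypes[!is.na(genotypes)]
  if (!all(bad %in% c(0, 2))) {
    stop("genotype dosages must be 0, 2 or NA (inbred homozygous coding)")
  }
  req <- c("snp_id", "chrom", "pos", "major", "minor")
  if (!all(req %in% names(snp_map))) {
    stop("snp_map must have columns: ", paste(req, collapse = ", "))
  }
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  # market classes must nest within landraces
  tab <- unique(line_info[, c("landrace", "market_class")])
  if (anyDuplicated(tab$market_class)) {
    stop("each market class must belong to exactly one landrace")
  }
  rownames(genotypes) <- line_info$line_id
  colnames(genotypes) <- snp_map$snp_id
  structure(
    list(genotypes = genotypes, snp_map = as.data.frame(snp_map),
         line_info = as.data.frame(line_info)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d lines x %d SNPs on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes), length(unique(x$snp_map$chrom))))
  cat("  landraces:    ", paste(sprintf("%s (%d)", names(table(x$line_info$landrace)),
                                        table(x$line_info$landrace)), collapse = ", "), "\n")
  cat("  market classes:", paste(unique(x$line_info$market_class), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

# default market-class composition: classes nest in landraces as in Middle
# American bean germplasm (navy/black from Mesoamerica; the rest Durango)
default_market_classes <- function() {
  list(
    Durango      = c(pinto = 0.42, great_northern = 0.25, pink = 0.15, small_red = 0.18),
    Mesoamerica  = c(black = 0.5, navy = 0.5)
  )
}

#' Simulate a structured inbred genotype panel
#'
#' Generates biallelic SNP genotypes for inbred lines from two landraces with
#' a Balding-Nichols differentiation model and blocky within-chromosome
#' linkage disequilibrium. Chromosomes are partitioned into haplotype blocks
#' by a first-order Markov process: walking along the map, a new block starts
#' at each SNP with probability \code{1 - exp(-d / ld_block_length)} (d = bp
#' gap), so block lengths are approximately geometric with the given mean.
#' Each block draws one ancestral frequency (Uniform(0.05, 0.5)) and one
#' landrace-specific frequency from the Balding-Nichols Beta with shape
#' parameters \code{p(1-fst)/fst} and \code{(1-p)(1-fst)/fst}; every SNP in
#' the block shares it. Each line draws one latent uniform per block, which
#' every SNP in the block copies except with probability
#' \code{within_block_noise} (fresh draw), so within-block
#' \code{r^2 ~ (1 - within_block_noise)^2} while cross-block LD is near
#' zero and decay in distance follows \code{exp(-d / ld_block_length)}.
#' Lines are homozygous at every locus (dosage 0 or 2).
#'
#' @param n_lines_per_landrace named integer vector of line counts, e.g.
#'   \code{c(Durango = 198, Mesoamerica = 101)} (the default, a 299-line
#'   panel).
#' @param n_snps total SNP count, spread evenly over \code{n_chrom}
#'   chromosomes.
#' @param fst differentiation between landraces, in (0, 1).
#' @param ld_block_length mean LD block length in bp.
#' @param n_chrom number of chromosomes (named Pv01..PvNN).
#' @param chrom_length_bp chromosome length used to place SNPs.
#' @param market_classes named list (per landrace) of market-class
#'   proportions; defaults to a six-class composition nested in the two
#'   landraces.
#' @param within_block_noise per-SNP probability of breaking out of its
#'   block's shared latent value (controls within-block r^2; default 0.1).
#' @param missing_rate fraction of calls set missing at random.
#' @param seed integer seed; identical seeds give identical panels.
#'
#' @return A \code{\link{genotype_panel}}.
#' @export
simulate_genotype_panel <- function(n_lines_per_landrace = c(Durango = 198, Mesoamerica = 101),
                                    n_snps = 2000,
                                    fst = 0.15,
                                    ld_block_length = 2e5,
                                    n_chrom = 11,
                                    chrom_length_bp = 5e7,
                                    market_classes = default_market_classes(),
                                    within_block_noise = 0.1,
                                    missing_rate = 0,
                                    seed = 1L) {
  if (any(n_lines_per_landrace <= 0)) stop("n_lines_per_landrace must be positive")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (length(n_lines_per_landrace) != 2 || is.null(names(n_lines_per_landrace))) {
    stop("n_lines_per_landrace must be a named vector of two landrace counts")
  }
  with_seed(seed, {
    landraces <- names(n_lines_per_landrace)
    n_total <- sum(n_lines_per_landrace)

    # SNP map: spread SNPs over chromosomes, sorted uniform positions
    chrom_names <- sprintf("Pv%02d", seq_len(n_chrom))
    per_chrom <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
    map <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      k <- per_chrom[i]
      if (k == 0) return(NULL)
      pos <- sort(sample.int(chrom_length_bp, k))
      data.frame(chrom = chrom_names[i], pos = pos)
    }))
    m <- nrow(map)
    alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), ncol = 2)
    same <- alleles[, 1] == alleles[, 2]
    alleles[same, 2] <- ifelse(alleles[same, 1] == "A", "G", "A")
    map$snp_id <- paste0(map$chrom, "_", map$pos)
    map$major <- alleles[, 1]
    map$minor <- alleles[, 2]
    map <- map[, c("snp_id", "chrom", "pos", "major", "minor")]

    # haplotype blocks: Markov block boundaries along each chromosome
    block <- integer(m)
    b <- 0L
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      d <- c(Inf, diff(map$pos[idx]))
      new_block <- runif(length(idx)) >= exp(-d / ld_block_length)
      new_block[1] <- TRUE
      block[idx] <- b + cumsum(new_block)
      b <- block[idx[length(idx)]]
    }
    n_blocks <- max(block)

    # one ancestral + landrace-specific frequency per block (Balding-Nichols)
    p_anc <- runif(n_blocks, 0.05, 0.5)
    a <- p_anc * (1 - fst) / fst
    bb <- (1 - p_anc) * (1 - fst) / fst
    freq_block <- sapply(landraces, function(l) {
      pmin(pmax(rbeta(n_blocks, a, bb), 1e-4), 1 - 1e-4)
    })

    geno <- matrix(0, n_total, m)
    line_land <- rep(landraces, n_lines_per_landrace)
    for (i in seq_len(n_total)) {
      f <- freq_block[block, line_land[i]]
      u <- runif(n_blocks)[block]             # shared latent value per block
      jitter <- runif(m) < within_block_noise # per-SNP breakout
      u[jitter] <- runif(sum(jitter))
      geno[i, ] <- 2 * (u < f)
    }
    if (missing_rate > 0) {
      geno[runif(length(geno)) < missing_rate] <- NA
    }

    # assign market classes within landrace by fixed proportions
    mc <- character(n_total)
    for (l in landraces) {
      idx <- which(line_land == l)
      props <- market_classes[[l]]
      if (is.null(props)) props <- setNames(1, paste0(l, "_class"))
      counts <- floor(props * length(idx))
      rem <- length(idx) - sum(counts)
      if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
      mc[idx] <- rep(names(props), counts)
    }
    line_info <- data.frame(
      line_id = sprintf("L%03d", seq_len(n_total)),
      landrace = line_land,
      market_class = mc,
      stringsAsFactors = FALSE
    )
    genotype_panel(geno, map, line_info)
  })
}

#' Minor allele frequency per SNP
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @return numeric vector of per-SNP minor allele frequencies over
#'   non-missing calls (dosage mean / 2).
#' @export
minor_allele_freq <- function(panel) {
  colMeans(panel$genotypes, na.rm = TRUE) / 2
}

# subset a panel by SNP and/or line index
subset_panel <- function(panel, snps = NULL, lines = NULL) {
  g <- panel$genotypes
  map <- panel$snp_map
  info <- panel$line_info
  if (!is.null(snps)) {
    g <- g[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  if (!is.null(lines)) {
    g <- g[lines, , drop = FALSE]
    info <- info[lines, , drop = FALSE]
  }
  genotype_panel(g, map, info)
}
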