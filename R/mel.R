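#' Bin significant associations along the genome
#'
#' Assigns every significant association to a fixed-width genomic bin
#' (default 0.1 Mb, half-open \code{[k*bin, (k+1)*bin)}; a SNP at an exact
#' boundary belongs to the upper bin) and summarizes each bin's contributing
#' traits and donors.
#'
#' @param assoc association table with columns \code{donor}, \code{trait},
#'   \code{snp_id}, \code{chrom}, \code{pos}, \code{significant} (rows from
#'   several per-trait scans stacked together).
#' @param bin_bp bin width in bp (default 1e5).
#' @return data.frame per non-empty bin: \code{bin_id}, \code{chrom},
#'   \code{bin_index}, \code{start}, \code{end}, \code{n_traits} (distinct
#'   (donor, trait) pairs), \code{n_trait_names} (distinct trait names),
#'   \code{n_donors}, plus list columns \code{snps} and \code{pairs}.
#' @export
bin_associations <- function(assoc, bin_bp = 1e5) {
  sig <- assoc[assoc$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(bin_id = character(0), chrom = character(0),
                      bin_index = integer(0), start = numeric(0),
                      end = numeric(0), n_traits = integer(0),
                      n_trait_names = integer(0), n_donors = integer(0)))
  }
  bi <- bin_index(sig$pos, bin_bp)
  sig$bin_id <- paste0(sig$chrom, ":", bi)
  out <- do.call(rbind, lapply(split(sig, sig$bin_id), function(b) {
    pairs <- unique(paste(b$donor, b$trait, sep = "|"))
    k <- bin_index(b$pos[1], bin_bp)
    df <- data.frame(bin_id = b$bin_id[1], chrom = b$chrom[1], bin_index = k,
                     start = k * bin_bp, end = (k + 1) * bin_bp,
                     n_traits = length(pairs),
                     n_trait_names = length(unique(b$trait)),
                     n_donors = length(unique(b$donor)),
                     stringsAsFactors = FALSE)
    df$snps <- list(unique(b$snp_id))
    df$pairs <- list(pairs)
    df
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$bin_index), , drop = FALSE]
}

#' Call multiple-effect loci (MEL) from binned associations
#'
#' Seed bins are bins whose significant SNPs are hit by at least
#' \code{min_traits} traits from at least \code{min_donors} donor
#' microbiomes. Each seed bin's boundary set is its significant SNPs plus
#' every panel SNP within \code{search_window_bp} of them with LD
#' \code{r^2 >= r2_threshold} to any of them, regardless of distance within
#' the window; the MEL interval spans the minimum to maximum position of the
#' boundary set. Overlapping intervals on the same chromosome are merged
#' with their provenance retained. A stringent tier flags regions with more
#' than \code{stringent_traits} contributing (donor, trait) pairs.
#'
#' @param bins output of \code{\link{bin_associations}}.
#' @param assoc the stacked association table the bins came from.
#' @param panel a \code{\link{genotype_panel}} (for LD computation).
#' @param min_traits minimum distinct contributing traits (default 5).
#' @param min_donors minimum distinct donors (default 2).
#' @param r2_threshold LD threshold defining the boundaries (default 0.75).
#' @param search_window_bp how far from the seed SNPs to search for linked
#'   SNPs (default 5 Mb).
#' @param count_by count traits as distinct (donor, trait) pairs
#'   (\code{"donor_trait"}, default) or distinct trait names
#'   (\code{"trait_name"}).
#' @param stringent_traits threshold for the stringent annotation tier
#'   (default 15: flagged when the count exceeds it).
#' @return data.frame of MEL regions: \code{mel_id}, \code{chrom},
#'   \code{start}, \code{end} (bp span of the boundary SNP set),
#'   \code{n_traits}, \code{n_donors}, \code{stringent}, plus list columns
#'   \code{seed_bins}, \code{member_snps}, \code{pairs}. Empty when nothing
#'   qualifies.
#' @export
call_mel <- function(bins, assoc, panel, min_traits = 5L, min_donors = 2L,
                     r2_threshold = 0.75, search_window_bp = 5e6,
                     count_by = c("donor_trait", "trait_name"),
                     stringent_traits = 15L) {
  count_by <- match.arg(count_by)
  if (nrow(bins) == 0) return(empty_mel())
  n_col <- if (count_by == "donor_trait") "n_traits" else "n_trait_names"
  seeds <- bins[bins[[n_col]] >= min_traits & bins$n_donors >= min_donors, ,
                drop = FALSE]
  if (nrow(seeds) == 0) return(empty_mel())

  map <- panel$snp_map
  regions <- lapply(seq_len(nrow(seeds)), function(i) {
    sb <- seeds[i, ]
    seed_snps <- sb$snps[[1]]
    seed_idx <- match(seed_snps, map$snp_id)
    lo <- min(map$pos[seed_idx]) - search_window_bp
    hi <- max(map$pos[seed_idx]) + search_window_bp
    cand <- which(map$chrom == sb$chrom & map$pos >= lo & map$pos <= hi)
    linked <- rep(FALSE, length(cand))
    for (j in seed_idx) {
      r2 <- ld_r2_vec(panel$genotypes[, j], panel$genotypes[, cand, drop = FALSE])
      linked <- linked | (!is.na(r2) & r2 >= r2_threshold)
    }
    members <- union(seed_snps, map$snp_id[cand[linked]])
    pos <- map$pos[match(members, map$snp_id)]
    list(chrom = sb$chrom, start = min(pos), end = max(pos),
         seed_bins = sb$bin_id, member_snps = members, pairs = sb$pairs[[1]])
  })

  # merge overlapping regions per chromosome, keeping provenance
  regions <- regions[order(vapply(regions, `[[`, "", "chrom"),
                           vapply(regions, `[[`, 0, "start"))]
  merged <- list()
  for (r in regions) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chrom == r$chrom && r$start <= last$end) {
      last$end <- max(last$end, r$end)
      last$start <- min(last$start, r$start)
      last$seed_bins <- union(last$seed_bins, r$seed_bins)
      last$member_snps <- union(last$member_snps, r$member_snps)
      last$pairs <- union(last$pairs, r$pairs)
      merged[[length(merged)]] <- last
    } else {
      merged <- c(merged, list(r))
    }
  }
  out <- do.call(rbind, lapply(seq_along(merged), function(i) {
    r <- merged[[i]]
    donors <- unique(sub("\\|.*$", "", r$pairs))
    traits <- if (count_by == "donor_trait") r$pairs else
      unique(sub("^[^|]*\\|", "", r$pairs))
    df <- data.frame(mel_id = paste0("MEL-", LETTERS[i]), chrom = r$chrom,
                     start = r$start, end = r$end,
                     n_traits = length(traits), n_donors = length(donors),
                     stringent = length(traits) > stringent_traits,
                     stringsAsFactors = FALSE)
    df$seed_bins <- list(r$seed_bins)
    df$member_snps <- list(r$member_snps)
    df$pairs <- list(r$pairs)
    df
  }))
  rownames(out) <- NULL
  out
}

empty_mel <- function() {
  data.frame(mel_id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), n_traits = integer(0), n_donors = integer(0),
             stringent = logical(0))
}

#' Allelic effects at a focal SNP
#'
#' Summarizes a line-level trait by homozygous genotype class (major = dosage
#' 0, minor = dosage 2), overall and within market class. Missing calls are
#' excluded; a class with a single line is reported with an undefined (NA)
#' SD.
#'
#' @param trait named numeric vector of line-level trait values.
#' @param panel a \code{\link{genotype_panel}}.
#' @param focal_snp SNP id.
#' @return list with \code{overall} (data.frame per genotype class: n, mean,
#'   sd), \code{by_market_class}, and \code{effect} = mean(minor) -
#'   mean(major).
#' @export
allelic_effects <- function(trait, panel, focal_snp) {
  j <- match(focal_snp, panel$snp_map$snp_id)
  if (is.na(j)) stop("focal SNP not found: ", focal_snp)
  lines <- intersect(names(trait), panel$line_info$line_id)
  dose <- panel$genotypes[lines, j]
  ok <- !is.na(dose)
  lines <- lines[ok]; dose <- dose[ok]
  cls <- ifelse(dose == 0, "major", "minor")
  if (!all(c("major", "minor") %in% cls)) {
    stop("both homozygous classes must be observed at ", focal_snp)
  }
  summarize <- function(values, classes) {
    do.call(rbind, lapply(c("major", "minor"), function(cl) {
      v <- values[classes == cl]
      data.frame(class = cl, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_)
    }))
  }
  overall <- summarize(trait[lines], cls)
  mc <- panel$line_info$market_class[match(lines, panel$line_info$line_id)]
  by_mc <- do.call(rbind, lapply(unique(mc), function(m) {
    sel <- mc == m
    cbind(market_class = m, summarize(trait[lines][sel], cls[sel]))
  }))
  list(overall = overall, by_market_class = by_mc,
       effect = overall$mean[overall$class == "minor"] -
         overall$mean[overall$class == "major"])
}

#' Log2 fold change between group means
#'
#' \code{log2((mean(minor) + pseudo) / (mean(major) + pseudo))}; used
#' identically for genotype-class contrasts, pooled-validation contrasts and
#' complementation (spiked vs unspiked) contrasts.
#'
#' @param minor,major numeric vectors (or scalars) of relative abundances in
#'   the two groups.
#' @param pseudo small positive stabilizer (default 1e-6).
#' @return log2 fold change; 0 with attribute \code{"undefined" = TRUE} when
#'   both means are zero.
#' @export
log2_fold_change <- function(minor, major, pseudo = 1e-6) {
  m1 <- mean(minor, na.rm = TRUE)
  m0 <- mean(major, na.rm = TRUE)
  if (m1 == 0 && m0 == 0) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  log2((m1 + pseudo) / (m0 + pseudo))
}

#' Concordance between two sets of per-trait fold changes
#'
#' Used to compare allelic responses between the mapping panel and a
#' validation (or complementation) experiment: counts traits whose log2
#' fold changes have matching nonzero signs and reports the Spearman
#' correlation over the shared traits.
#'
#' @param fc_reference,fc_test named numeric vectors of per-trait log2 fold
#'   changes (>= 3 shared names).
#' @return list with \code{n_shared}, \code{agree} (count),
#'   \code{agreement} (fraction), \code{rho}, \code{p}.
#' @export
concordance <- function(fc_reference, fc_test) {
  shared <- intersect(names(fc_reference), names(fc_test))
  if (length(shared) < 3) stop("at least 3 shared traits are required")
  a <- fc_reference[shared]; b <- fc_test[shared]
  agree <- sum(sign(a) == sign(b) & sign(a) != 0)
  sp <- spearman_cor(a, b)
  list(n_shared = length(shared), agree = agree,
       agreement = agree / length(shared), rho = sp$rho, p = sp$p)
}
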