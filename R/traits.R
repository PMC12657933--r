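# Count tables are numeric matrices, samples in rows and features in
# columns, with sample ids as rownames. Transform provenance travels as the
# "provenance" attribute (a list) so downstream writers can record it.

add_provenance <- function(x, ...) {
  prov <- c(attr(x, "provenance") %||% list(), list(...))
  attr(x, "provenance") <- prov
  x
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' \code{depth}. Samples with fewer than \code{depth} total reads are dropped
#' with a warning.
#'
#' @param counts samples x features nonnegative integer matrix.
#' @param depth target depth (default 7197 reads).
#' @param seed integer seed.
#' @return rarefied count matrix (every row sums to \code{depth}).
#' @export
rarefy <- function(counts, depth = 7197L, seed = 1L) {
  if (depth <= 0) stop("depth must be >= 1")
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("%d sample(s) below depth %d dropped: %s", sum(drop), depth,
                    paste(head(rownames(counts)[drop], 5), collapse = ", ")),
            call. = FALSE)
    counts <- counts[!drop, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no samples at or above the rarefaction depth")
  out <- with_seed(seed, {
    t(apply(counts, 1, function(x) {
      reads <- rep.int(seq_along(x), x)
      keep <- sample(reads, depth)
      tabulate(keep, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(counts)
  add_provenance(out, rarefied_depth = depth, rarefy_seed = seed)
}

#' Prevalence and mean-relative-abundance feature filter
#'
#' Removes features detected in fewer than \code{min_prevalence} of samples
#' or whose mean relative abundance is below \code{min_mean_relab}
#' (defaults: 10 percent prevalence, 0.15 percent abundance). When
#' \code{donor} is supplied the filter is applied within each donor's samples
#' separately ("by subject") and a named list of per-donor tables is
#' returned.
#'
#' @param counts samples x features count matrix.
#' @param min_prevalence fraction of samples a feature must be detected in.
#' @param min_mean_relab minimum mean relative abundance.
#' @param donor optional per-sample donor ids (length nrow(counts)).
#' @return filtered matrix, or named list of matrices when \code{donor} is
#'   given.
#' @export
filter_taxa <- function(counts, min_prevalence = 0.10, min_mean_relab = 0.0015,
                        donor = NULL) {
  if (min_prevalence < 0 || min_prevalence > 1 || min_mean_relab < 0 || min_mean_relab > 1) {
    stop("filter fractions must lie in [0, 1]")
  }
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty feature table")
  if (!is.null(donor)) {
    stopifnot(length(donor) == nrow(counts))
    return(lapply(split(seq_len(nrow(counts)), donor), function(idx) {
      filter_taxa(counts[idx, , drop = FALSE], min_prevalence, min_mean_relab)
    }))
  }
  prev <- colMeans(counts > 0)
  relab <- counts / rowSums(counts)
  mean_relab <- colMeans(relab)
  keep <- prev >= min_prevalence & mean_relab >= min_mean_relab
  out <- counts[, keep, drop = FALSE]
  add_provenance(out, filter_min_prevalence = min_prevalence,
                 filter_min_mean_relab = min_mean_relab,
                 filter_removed = sum(!keep))
}

#' Log2-transformed abundances
#'
#' @param counts samples x features nonnegative matrix.
#' @param pseudocount added before the log (default 1, so zero counts map to
#'   0).
#' @return matrix of \code{log2(count + pseudocount)} with provenance.
#' @export
log2_abundance <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  out <- log2(counts + pseudocount)
  add_provenance(out, log2_pseudocount = pseudocount)
}

#' Centered log-ratio transform
#'
#' Applies the CLR transform to compositional rows:
#' \code{clr(x)_i = ln(x_i) - mean_j ln(x_j)}. Zeros are handled by
#' multiplicative replacement: each zero is replaced by
#' \code{zero_replace} (in count units, or as a fraction of the row total
#' when the input is already relative), and the row re-closed.
#'
#' @param x samples x features matrix of counts or relative abundances.
#' @param zero_replace replacement value for zeros before closure (default
#'   0.5 count units).
#' @return CLR matrix; every row sums to zero.
#' @export
clr_transform <- function(x, zero_replace = 0.5) {
  x <- as.matrix(x)
  if (any(rowSums(x) == 0)) stop("all-zero rows cannot be CLR-transformed")
  x[x == 0] <- zero_replace
  rel <- x / rowSums(x)
  lx <- log(rel)
  out <- lx - rowMeans(lx)
  add_provenance(out, clr_zero_replace = zero_replace)
}

#' Alpha diversity of a single sample
#'
#' @param counts nonnegative count vector with at least one positive entry.
#' @param metric one of \code{"shannon"}, \code{"simpson"}, \code{"pielou"},
#'   \code{"observed"}, \code{"chao1"}.
#' @param base logarithm base for Shannon/Pielou (default \code{exp(1)};
#'   2 is also common).
#' @return scalar diversity value. Simpson is the Gini-Simpson index
#'   \code{1 - sum(p^2)}; Chao1 uses the bias-corrected estimator
#'   \code{S + F1(F1-1)/(2(F2+1))} so singleton-only samples are defined.
#' @export
alpha_diversity <- function(counts, metric = c("shannon", "simpson", "pielou",
                                               "observed", "chao1"),
                            base = exp(1)) {
  metric <- match.arg(metric)
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be nonnegative with at least one positive entry")
  }
  p <- counts[counts > 0] / sum(counts)
  s_obs <- sum(counts > 0)
  switch(metric,
    shannon = -sum(p * log(p, base = base)),
    simpson = 1 - sum(p^2),
    pielou = {
      if (s_obs == 1) return(0)
      (-sum(p * log(p, base = base))) / log(s_obs, base = base)
    },
    observed = s_obs,
    chao1 = {
      f1 <- sum(counts == 1)
      f2 <- sum(counts == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    }
  )
}

#' Alpha-diversity table for all samples
#'
#' @param counts samples x features count matrix.
#' @param metrics diversity metrics to compute (see
#'   \code{\link{alpha_diversity}}).
#' @param base log base for Shannon/Pielou.
#' @return samples x metrics numeric matrix.
#' @export
alpha_diversity_table <- function(counts,
                                  metrics = c("shannon", "simpson", "pielou",
                                              "observed", "chao1"),
                                  base = exp(1)) {
  counts <- as.matrix(counts)
  out <- sapply(metrics, function(m) apply(counts, 1, alpha_diversity, metric = m, base = base))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), metrics))
  out
}

#' Aggregate features to a higher taxonomic rank
#'
#' @param counts samples x features count matrix (e.g. ASVs).
#' @param taxonomy named character vector mapping every feature to its label
#'   at the target rank (unmapped features may be bucketed by setting
#'   \code{unassigned}).
#' @param unassigned label used for features missing from \code{taxonomy};
#'   \code{NULL} (default) makes missing labels an error.
#' @return samples x labels matrix; per-sample totals are conserved.
#' @export
aggregate_taxonomy <- function(counts, taxonomy, unassigned = NULL) {
  counts <- as.matrix(counts)
  feats <- colnames(counts)
  lab <- taxonomy[feats]
  if (any(is.na(lab))) {
    if (is.null(unassigned)) {
      stop("taxonomy labels missing for: ",
           paste(head(feats[is.na(lab)], 5), collapse = ", "))
    }
    lab[is.na(lab)] <- unassigned
  }
  groups <- split(seq_along(lab), lab)
  out <- sapply(groups, function(j) rowSums(counts[, j, drop = FALSE]))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), names(groups)))
  out
}
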