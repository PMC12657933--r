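#' Minor-allele-frequency filter
#'
#' Retains SNPs whose minor allele frequency, computed over non-missing
#' calls, is strictly greater than \code{min_maf} (default 0.05, the usual
#' GWAS inclusion rule).
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param min_maf frequency threshold in [0, 0.5].
#' @return the filtered \code{genotype_panel}; the number of SNPs removed is
#'   attached as attribute \code{"n_removed"}.
#' @export
maf_filter <- function(panel, min_maf = 0.05) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  maf <- minor_allele_freq(panel)
  maf <- pmin(maf, 1 - maf)
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep)) {
    stop(sprintf("all %d SNPs removed at MAF > %g", length(keep), min_maf))
  }
  out <- subset_panel(panel, snps = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

# column-center the dosage matrix with per-SNP mean imputation of missing
centered_dosages <- function(panel) {
  g <- panel$genotypes
  mu <- colMeans(g, na.rm = TRUE)
  if (any(is.na(g))) {
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  sweep(g, 2, mu)
}

#' Centered kinship matrix
#'
#' \code{K = W W' / s} with \code{W} the column-centered dosage matrix
#' (missing calls mean-imputed per SNP) and the scale \code{s} chosen so
#' that the mean diagonal of \code{K} equals 1.
#'
#' @param panel a \code{\link{genotype_panel}} with at least two lines.
#' @return lines x lines symmetric kinship matrix, dimnames = line ids.
#' @export
centered_kinship <- function(panel) {
  if (nrow(panel$genotypes) < 2) stop("at least two lines are required")
  w <- centered_dosages(panel)
  if (all(abs(w) < .Machine$double.eps)) stop("zero-variance panel")
  k <- tcrossprod(w)
  k <- k * nrow(k) / sum(diag(k))
  dimnames(k) <- list(panel$line_info$line_id, panel$line_info$line_id)
  k
}

#' Genotype principal components
#'
#' Eigenvectors of the centered kinship matrix scaled by the square root of
#' their eigenvalues (line scores). Signs follow the deterministic
#' largest-magnitude-entry-positive convention.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param k number of components (must be below the number of lines).
#' @return lines x k score matrix with eigenvalues attached as attribute
#'   \code{"eigenvalues"}.
#' @export
genotype_pca <- function(panel, k = 3) {
  n <- nrow(panel$genotypes)
  if (k >= n) stop("k must be smaller than the number of lines")
  kin <- centered_kinship(panel)
  eg <- eigen(kin, symmetric = TRUE)
  if (eg$values[k] <= 1e-12) stop("k exceeds the rank of the kinship matrix")
  v <- fix_signs(eg$vectors[, seq_len(k), drop = FALSE])
  scores <- sweep(v, 2, sqrt(eg$values[seq_len(k)]), "*")
  dimnames(scores) <- list(panel$line_info$line_id, paste0("PC", seq_len(k)))
  attr(scores, "eigenvalues") <- eg$values[seq_len(k)]
  scores
}

#' Linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over jointly
#' non-missing lines (composite LD; exact for inbred homozygous coding,
#' where dosage correlation equals gametic correlation).
#'
#' @param g1,g2 dosage vectors in \{0, 2, NA\} of equal length.
#' @return r^2 in [0, 1], or \code{NA} with a warning if either SNP is
#'   monomorphic among the jointly non-missing lines.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  x <- g1[ok]; y <- g2[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) {
    warning("monomorphic SNP: LD undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)^2
}

# r^2 of one focal SNP against a dosage matrix (columns = SNPs), pairwise
# complete; monomorphic columns give NA without warnings (bulk path used by
# the MEL boundary search)
ld_r2_vec <- function(g_focal, g_mat) {
  apply(g_mat, 2, function(col) {
    ok <- !is.na(g_focal) & !is.na(col)
    x <- g_focal[ok]; y <- col[ok]
    if (length(x) < 2) return(NA_real_)
    sx <- sd(x); sy <- sd(y)
    if (sx == 0 || sy == 0) return(NA_real_)
    cor(x, y)^2
  })
}
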