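#' Bonferroni per-test threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @return per-test p-value threshold \code{alpha / m}.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m
}

#' Single-marker association scan
#'
#' For each SNP, fits the least-squares model
#' \code{blup ~ intercept + PCs (+ covariates) + dosage} and reports the
#' Wald test of the dosage term. Missing dosages are handled by per-SNP
#' complete-case fitting; SNPs monomorphic or collinear with the covariates
#' after missingness are flagged (\code{p = NA}) and not counted as tests.
#'
#' @param blups named numeric vector of line-level trait values (BLUPs).
#' @param panel a \code{\link{genotype_panel}} (MAF-filtered).
#' @param pcs optional matrix of genotype principal components (rownames =
#'   line ids); conventionally the first five.
#' @param covariates optional extra covariate matrix (rownames = line ids),
#'   e.g. pseudo-QTN dosages.
#' @param alpha family-wise error rate used for the Bonferroni significance
#'   flags (default 0.05).
#' @return data.frame (snp_id, chrom, pos, effect, se, p, lod, significant)
#'   with the per-test threshold in attribute \code{"threshold"} and the
#'   number of tests in \code{"n_tests"}. LOD is \code{-log10(p)}.
#' @export
single_marker_scan <- function(blups, panel, pcs = NULL, covariates = NULL,
                               alpha = 0.05) {
  lines <- intersect(names(blups), panel$line_info$line_id)
  if (length(lines) < 3) stop("too few lines shared between traits and panel")
  y <- blups[lines]
  g <- panel$genotypes[lines, , drop = FALSE]
  C <- matrix(1, length(lines), 1)
  if (!is.null(pcs)) C <- cbind(C, as.matrix(pcs)[lines, , drop = FALSE])
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates)[lines, , drop = FALSE])
  n <- length(y)
  qr_c <- qr(C)
  p_cov <- qr_c$rank
  df <- n - p_cov - 1L
  if (df < 1) stop("not enough residual degrees of freedom for the scan")

  m <- ncol(g)
  effect <- se <- pval <- rep(NA_real_, m)
  has_na <- colSums(is.na(g)) > 0

  # fast path: residualize trait and complete SNP columns on the covariates
  ry <- qr.resid(qr_c, y)
  if (any(!has_na)) {
    gc <- g[, !has_na, drop = FALSE]
    rg <- qr.resid(qr_c, gc)
    sxx <- colSums(rg^2)
    testable <- sxx > 1e-10
    b <- rep(NA_real_, ncol(gc))
    b[testable] <- colSums(rg[, testable, drop = FALSE] * ry) / sxx[testable]
    rss <- sum(ry^2) - b^2 * sxx
    s2 <- rss / df
    se_j <- sqrt(s2 / sxx)
    t_j <- b / se_j
    p_j <- 2 * pt(-abs(t_j), df = df)
    idx <- which(!has_na)
    effect[idx] <- b; se[idx] <- se_j; pval[idx] <- ifelse(testable, p_j, NA)
  }
  # complete-case loop for SNPs with missing calls
  for (j in which(has_na)) {
    ok <- !is.na(g[, j])
    if (sum(ok) <= p_cov + 1) next
    x <- g[ok, j]
    if (sd(x) == 0) next
    fit <- lm(y[ok] ~ C[ok, -1, drop = FALSE] + x)
    cf <- summary(fit)$coefficients
    if (!"x" %in% rownames(cf)) next
    effect[j] <- cf["x", 1]; se[j] <- cf["x", 2]; pval[j] <- cf["x", 4]
  }

  n_tests <- sum(!is.na(pval))
  thr <- bonferroni_threshold(alpha, max(n_tests, 1))
  out <- data.frame(
    snp_id = panel$snp_map$snp_id, chrom = panel$snp_map$chrom,
    pos = panel$snp_map$pos, effect = effect, se = se, p = pval,
    lod = -log10(pval), significant = !is.na(pval) & pval < thr,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  attr(out, "n_tests") <- n_tests
  out
}

# assign positions to half-open bins [k*bin_bp, (k+1)*bin_bp); a SNP at an
# exact boundary belongs to the upper bin
bin_index <- function(pos, bin_bp) as.integer(pos %/% bin_bp)

#' Conditioned association scan with pseudo-QTN covariates
#'
#' An iterated marginal scan in the spirit of multi-locus mixed models:
#' each pass selects Bonferroni-significant SNPs, keeps the strongest per
#' genomic bin, prunes candidates in LD (\code{r^2 >=} \code{r2_prune}) with
#' an already-kept candidate, caps the set at \code{max_pseudo_qtn}, and
#' re-scans with the kept pseudo-QTNs as fixed covariates — excluding, for
#' each tested SNP, any pseudo-QTN in the tested SNP's own bin so a signal
#' is never conditioned on itself. Iteration stops when the pseudo-QTN set
#' repeats or after \code{max_iter} passes.
#'
#' @inheritParams single_marker_scan
#' @param max_iter maximum number of scan passes (default 10).
#' @param bin_bp bin width for pseudo-QTN selection and exclusion (default
#'   1 Mb).
#' @param max_pseudo_qtn cap on the pseudo-QTN set (default 10).
#' @param r2_prune LD pruning threshold among candidates (default 0.7).
#' @return association table as in \code{\link{single_marker_scan}}, with
#'   the final pseudo-QTN ids in attribute \code{"pseudo_qtn"} and the
#'   number of passes in \code{"n_passes"}.
#' @export
conditioned_scan <- function(blups, panel, pcs = NULL, alpha = 0.05,
                             max_iter = 10L, bin_bp = 1e6,
                             max_pseudo_qtn = 10L, r2_prune = 0.7) {
  lines <- intersect(names(blups), panel$line_info$line_id)
  g_all <- panel$genotypes[lines, , drop = FALSE]
  map <- panel$snp_map
  bins <- paste(map$chrom, bin_index(map$pos, bin_bp))

  qtn_dosage <- function(ids) {
    d <- g_all[, ids, drop = FALSE]
    for (j in seq_len(ncol(d))) {
      nas <- is.na(d[, j])
      if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
    }
    d
  }

  select_qtn <- function(tab) {
    sig <- tab[tab$significant %in% TRUE, , drop = FALSE]
    if (nrow(sig) == 0) return(character(0))
    sig <- sig[order(sig$p), , drop = FALSE]
    sig_bins <- bins[match(sig$snp_id, map$snp_id)]
    sig <- sig[!duplicated(sig_bins), , drop = FALSE] # best per bin
    kept <- character(0)
    for (id in sig$snp_id) {
      if (length(kept) >= max_pseudo_qtn) break
      if (length(kept)) {
        r2 <- ld_r2_vec(g_all[, id], g_all[, kept, drop = FALSE])
        if (any(r2 >= r2_prune, na.rm = TRUE)) next
      }
      kept <- c(kept, id)
    }
    kept
  }

  tab <- single_marker_scan(blups, panel, pcs, alpha = alpha)
  history <- list(character(0))
  qtn <- select_qtn(tab)
  n_passes <- 1L
  while (n_passes < max_iter) {
    key <- paste(sort(qtn), collapse = ",")
    if (key %in% vapply(history, function(h) paste(sort(h), collapse = ","), "")) break
    history <- c(history, list(qtn))
    if (length(qtn) == 0) break
    # group tested SNPs by which pseudo-QTN shares their bin
    qtn_bins <- bins[match(qtn, map$snp_id)]
    snp_excl <- lapply(seq_along(map$snp_id), function(j) qtn[qtn_bins == bins[j]])
    excl_key <- vapply(snp_excl, paste, "", collapse = ",")
    tab_new <- tab
    for (ek in unique(excl_key)) {
      use_qtn <- setdiff(qtn, strsplit(ek, ",")[[1]])
      cov <- if (length(use_qtn)) qtn_dosage(use_qtn) else NULL
      sub_idx <- which(excl_key == ek)
      sub_panel <- subset_panel(panel, snps = sub_idx)
      sub_tab <- single_marker_scan(blups, sub_panel, pcs, covariates = cov,
                                    alpha = alpha)
      tab_new[sub_idx, c("effect", "se", "p", "lod")] <-
        sub_tab[, c("effect", "se", "p", "lod")]
    }
    n_tests <- sum(!is.na(tab_new$p))
    thr <- bonferroni_threshold(alpha, max(n_tests, 1))
    tab_new$significant <- !is.na(tab_new$p) & tab_new$p < thr
    attr(tab_new, "threshold") <- thr
    attr(tab_new, "n_tests") <- n_tests
    tab <- tab_new
    n_passes <- n_passes + 1L
    qtn <- select_qtn(tab)
  }
  attr(tab, "pseudo_qtn") <- qtn
  attr(tab, "n_passes") <- n_passes
  tab
}
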