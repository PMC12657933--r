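#' Bray-Curtis dissimilarity
#'
#' \code{d(x, y) = sum|x - y| / sum(x + y)} over feature abundances.
#' Computed with \code{vegan::vegdist}; pairs of all-zero samples are
#' undefined and returned as \code{NaN} with a warning.
#'
#' @param x samples x features nonnegative abundance matrix.
#' @return a \code{dist} object with attribute \code{metric = "bray"}.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be nonnegative")
  zero <- rowSums(x) == 0
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (sum(zero) >= 2) {
    warning("distance between all-zero samples is undefined (NaN)", call. = FALSE)
  }
  attr(d, "metric") <- "bray"
  d
}

#' Mean distance from a donor's blank controls
#'
#' For every non-blank sample, the mean dissimilarity to the blank
#' (substrate-free) fermentation wells of the same donor — a scalar summary
#' of how far the substrate pushed the community from its unfed baseline.
#'
#' @param d a \code{dist} or square distance matrix over samples.
#' @param donor named character vector: donor id per sample (names = sample
#'   ids matching the distance labels).
#' @param blank logical vector (same order) flagging blank wells.
#' @return named numeric vector over non-blank samples.
#' @export
distance_from_blank <- function(d, donor, blank) {
  m <- as.matrix(d)
  ids <- rownames(m)
  stopifnot(length(donor) == nrow(m), length(blank) == nrow(m))
  out <- setNames(rep(NA_real_, sum(!blank)), ids[!blank])
  for (dn in unique(donor)) {
    bl <- which(donor == dn & blank)
    if (length(bl) == 0) stop("donor without blank wells: ", dn)
    sm <- which(donor == dn & !blank)
    out[ids[sm]] <- rowMeans(m[sm, bl, drop = FALSE])
  }
  out[!is.na(out)]
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Anderson's pseudo-F from among/within sums of squared dissimilarities,
#' with a seeded label-permutation test. The p-value uses the
#' greater-or-equal counting rule with +1 smoothing:
#' \code{p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)}, so the minimal
#' attainable p at 999 permutations is 0.001.
#'
#' @param d a \code{dist} or square distance matrix.
#' @param labels group labels (>= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with \code{f} (pseudo-F), \code{r2} (among-group fraction of
#'   total SS), \code{p}, \code{n_perm}.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  m <- as.matrix(d)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("at least two groups are required")
  n <- nrow(m)
  stopifnot(length(labels) == n)
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  a <- nlevels(droplevels(labels))
  pseudo_f <- function(lab) {
    ss_within <- 0
    for (g in levels(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ss_among <- ss_total - ss_within
    (ss_among / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- pseudo_f(labels)
  ss_w <- 0
  for (g in levels(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  r2 <- (ss_total - ss_w) / ss_total
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pseudo_f(labels[sample.int(n)]) >= f_obs
    }, logical(1)))
  })
  list(f = f_obs, r2 = r2, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Kruskal-Wallis tests with Benjamini-Hochberg adjustment
#'
#' Runs a rank-based Kruskal-Wallis test per trait (column) against the group
#' labels and adjusts p-values across the traits with the BH step-up
#' procedure (one family per call). Constant traits get p = 1 with a
#' warning.
#'
#' @param traits samples x traits numeric matrix.
#' @param groups group labels (>= 2 groups).
#' @return data.frame (trait, statistic, df, p, p_adj).
#' @export
kruskal_bh <- function(traits, groups) {
  traits <- as.matrix(traits)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("at least two groups are required")
  res <- lapply(seq_len(ncol(traits)), function(j) {
    y <- traits[, j]
    if (length(unique(y[!is.na(y)])) < 2) {
      warning("constant trait '", colnames(traits)[j] %||% j,
              "': p set to 1", call. = FALSE)
      return(c(statistic = NA_real_, df = NA_real_, p = 1))
    }
    k <- kruskal.test(y, groups)
    c(statistic = unname(k$statistic), df = unname(k$parameter), p = k$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$trait <- colnames(traits) %||% paste0("trait", seq_len(ncol(traits)))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("trait", "statistic", "df", "p", "p_adj")]
}

#' Dunn's post hoc test
#'
#' Pairwise comparisons of mean ranks following a Kruskal-Wallis test, with
#' the tie-corrected standard error
#' \code{sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))},
#' \code{T = sum(t^3 - t) / (12(N - 1))}, and p-values adjusted across
#' pairs (BH by default, matching the trait-level adjustment).
#'
#' @param y numeric trait vector.
#' @param groups group labels.
#' @param p_adjust adjustment method for \code{stats::p.adjust}.
#' @return data.frame (group1, group2, z, p, p_adj).
#' @export
dunn_posthoc <- function(y, groups, p_adjust = "BH") {
  groups <- droplevels(as.factor(groups))
  ok <- !is.na(y)
  y <- y[ok]; groups <- groups[ok]
  if (any(table(groups) == 0)) stop("every group must contain observations")
  n <- length(y)
  r <- rank(y)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    (mean_rank[pr[1]] - mean_rank[pr[2]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = unname(z),
             p = unname(p), p_adj = p.adjust(p, method = p_adjust))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the large-sample t approximation
#' \code{t = rho sqrt((n - 2) / (1 - rho^2))} on \code{n - 2} degrees of
#' freedom for the p-value.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 paired values are required")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigen-decomposes it.
#' Negative eigenvalues (non-Euclidean distances) are reported, not dropped.
#'
#' @param d a \code{dist} or square distance matrix.
#' @param k number of axes to return.
#' @return list with \code{coordinates} (samples x k) and \code{eigenvalues}
#'   (all n - 1, including any negative ones).
#' @export
pcoa <- function(d, k = 2) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (k > n - 1) stop("k exceeds the maximal embedding dimension (n - 1)")
  sc <- cmdscale(stats::as.dist(m), k = k, eig = TRUE)
  coords <- sc$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = sc$eig)
}
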