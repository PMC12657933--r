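#' Select the core genera covering most of the community
#'
#' Genera are ordered by mean relative abundance (descending) and the
#' smallest prefix whose cumulative mean abundance reaches
#' \code{cumulative_threshold} is returned — the abundant organisms that
#' together account for at least 90 percent of the community under the
#' default.
#'
#' @param x samples x genera abundance matrix (counts or relative; rows are
#'   closed internally).
#' @param cumulative_threshold fraction of total abundance to cover, in
#'   (0, 1].
#' @return character vector of selected genus names, most abundant first.
#' @export
select_core_genera <- function(x, cumulative_threshold = 0.90) {
  if (cumulative_threshold <= 0 || cumulative_threshold > 1) {
    stop("cumulative_threshold must lie in (0, 1]")
  }
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty abundance table")
  rel <- x / rowSums(x)
  mean_rel <- sort(colMeans(rel), decreasing = TRUE)
  if (cumulative_threshold == 1) return(names(mean_rel)[mean_rel > 0])
  cum <- cumsum(mean_rel) / sum(mean_rel)
  k <- which(cum >= cumulative_threshold)[1]
  names(mean_rel)[seq_len(k)]
}

#' Sequential MANOVA sums-of-squares-and-cross-products decomposition
#'
#' Fits the multivariate fixed-effect model in the stated term order
#' (genotype, then digestion batch, then plate within batch) and returns
#' the sequential (Type-I) hypothesis SSCP matrix and degrees of freedom for
#' each term plus the residual SSCP. Each diagonal entry of a hypothesis
#' SSCP equals the classical univariate ANOVA sum of squares for that
#' response.
#'
#' @param y samples x variables response matrix (e.g. CLR abundances of the
#'   core genera).
#' @param genotype factor of genotype labels.
#' @param batch optional factor of digestion batches.
#' @param plate optional factor of plates; nested within batch when both are
#'   given.
#' @return list with \code{H} (named list of hypothesis SSCP matrices),
#'   \code{df} (named term degrees of freedom), \code{E} (error SSCP),
#'   \code{df_error}, and \code{terms} (fit order).
#' @export
manova_sscp <- function(y, genotype, batch = NULL, plate = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  dummy <- function(f) {
    # reference-level dummy coding; single-level factors contribute nothing
    f <- droplevels(as.factor(f))
    if (nlevels(f) < 2) return(matrix(0, length(f), 0))
    model.matrix(~f)[, -1, drop = FALSE]
  }
  genotype <- droplevels(as.factor(genotype))
  terms <- list(genotype = dummy(genotype))
  if (!is.null(batch)) terms$batch <- dummy(batch)
  if (!is.null(plate)) {
    pl <- if (!is.null(batch)) interaction(batch, plate, drop = TRUE) else plate
    terms$plate <- dummy(pl)
  }
  yc <- scale(y, center = TRUE, scale = FALSE)
  H <- list(); dfs <- numeric(0)
  x_cum <- matrix(1, n, 1) # intercept
  rank_prev <- 1L
  fit_prev <- matrix(colMeans(y), n, ncol(y), byrow = TRUE)
  for (tm in names(terms)) {
    x_cum <- cbind(x_cum, terms[[tm]])
    qr_cum <- qr(x_cum)
    fit_cum <- qr.fitted(qr_cum, y)
    inc <- fit_cum - fit_prev
    H[[tm]] <- crossprod(inc)
    dfs[tm] <- qr_cum$rank - rank_prev
    rank_prev <- qr_cum$rank
    fit_prev <- fit_cum
  }
  resid <- y - fit_prev
  df_e <- n - rank_prev
  if (df_e < 1) stop("saturated design: no residual degrees of freedom")
  dimnames_y <- list(colnames(y), colnames(y))
  H <- lapply(H, function(m) { dimnames(m) <- dimnames_y; m })
  E <- crossprod(resid); dimnames(E) <- dimnames_y
  list(H = H, df = dfs, E = E, df_error = df_e, terms = names(terms))
}

#' Convert an SSCP matrix to a (co)variance matrix
#'
#' @param sscp symmetric SSCP matrix.
#' @param df its degrees of freedom (> 0).
#' @return mean-square matrix \code{sscp / df}.
#' @export
sscp_to_cov <- function(sscp, df) {
  if (df <= 0) stop("degrees of freedom must be positive")
  sscp / df
}

#' Convert a covariance matrix to a correlation matrix
#'
#' @param v symmetric covariance matrix with strictly positive diagonal.
#' @return correlation matrix \code{v_ij / sqrt(v_ii v_jj)}.
#' @export
cov_to_corr <- function(v) {
  d <- diag(v)
  if (any(d <= 0)) stop("covariance diagonal must be strictly positive")
  s <- 1 / sqrt(d)
  out <- v * tcrossprod(s)
  diag(out) <- 1
  out
}

# EMS coefficient of the genotypic (co)variance in the genotype mean square:
# r for balanced r-replicate designs, (N - sum n_i^2 / N) / (g - 1) for
# unbalanced one-way replication.
ems_coefficient <- function(reps) {
  if (length(reps) == 1) return(as.numeric(reps))
  n_i <- as.numeric(reps)
  n_tot <- sum(n_i)
  g <- length(n_i)
  (n_tot - sum(n_i^2) / n_tot) / (g - 1)
}

#' Genetic covariance matrix from expected mean squares
#'
#' Solves the multivariate analog of the one-way expected-mean-square
#' equations: with genotype mean-square matrix \code{m_h} and error
#' mean-square matrix \code{m_e},
#' \code{Sigma_G = (m_h - m_e) / c}, where \code{c} is the coefficient of
#' the genotypic (co)variance in the expected genotype mean square
#' (\code{c = r} for balanced r-replicate designs,
#' \code{c = (N - sum n_i^2 / N) / (g - 1)} for unbalanced replication).
#' The result is a difference of matrices and need not be positive
#' semidefinite; an optional projection clips negative eigenvalues.
#'
#' @param m_h genotype hypothesis covariance (mean-square) matrix.
#' @param m_e error covariance (mean-square) matrix.
#' @param reps either a single replicate count (balanced) or the vector of
#'   per-genotype replicate counts.
#' @param project_psd clip negative eigenvalues to zero (default FALSE).
#' @return the genetic covariance matrix.
#' @export
genetic_covariance <- function(m_h, m_e, reps, project_psd = FALSE) {
  stopifnot(all(dim(m_h) == dim(m_e)))
  cc <- ems_coefficient(reps)
  if (cc <= 0) stop("EMS coefficient must be positive")
  out <- (m_h - m_e) / cc
  if (project_psd) {
    eg <- eigen(out, symmetric = TRUE)
    out <- eg$vectors %*% diag(pmax(eg$values, 0), nrow(out)) %*% t(eg$vectors)
    dimnames(out) <- dimnames(m_h)
  }
  out
}

# deterministic eigenvector sign: largest-magnitude entry positive
fix_signs <- function(v) {
  apply(v, 2, function(a) {
    j <- which.max(abs(a))
    if (length(j) == 1 && is.finite(a[j]) && a[j] < 0) -a else a
  })
}

#' Canonical discriminant analysis from SSCP matrices
#'
#' Solves the generalized eigenproblem \code{H a = lambda E a}, finding the
#' linear combinations of variables that maximize among-genotype relative to
#' within-genotype variation. Raw coefficients are scaled so that
#' \code{a' (E / df_e) a = 1} (unit within-group variance on the canonical
#' variate); standardized coefficients are the raw coefficients multiplied
#' by the within-group standard deviations \code{sqrt(diag(E / df_e))}.
#'
#' @param h genotype hypothesis SSCP matrix.
#' @param e error SSCP matrix.
#' @param df_e error degrees of freedom.
#' @param k number of canonical components retained (default 4).
#' @param ridge relative ridge added to \code{e} when it is numerically
#'   singular (\code{ridge * trace(e) / p} on the diagonal); a message is
#'   emitted when triggered.
#' @return list with \code{eigenvalues}, \code{raw} (p x k raw
#'   coefficients) and \code{standardized} (p x k).
#' @export
cda <- function(h, e, df_e, k = 4, ridge = 1e-8) {
  p <- nrow(e)
  if (k > p) stop("k exceeds the number of variables")
  chol_ok <- function(m) {
    ch <- tryCatch(chol(m), error = function(err) NULL)
    if (!is.null(ch) && min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
      return(NULL)
    }
    ch
  }
  e_eff <- e
  ch <- chol_ok(e_eff)
  if (is.null(ch)) {
    # CLR inputs make E rank-deficient by construction (rows sum to zero);
    # escalate the relative ridge until the Cholesky is well-conditioned
    message("cda: error SSCP near-singular; ridge applied")
    eps <- ridge
    repeat {
      e_eff <- e + diag(eps * sum(diag(e)) / p, p)
      ch <- chol_ok(e_eff)
      if (!is.null(ch) || eps > 1e-2) break
      eps <- eps * 100
    }
    if (is.null(ch)) stop("error SSCP singular; CDA not identifiable")
  }
  # L L' = E with L = t(ch); solve the symmetric eigenproblem of L^-1 H L^-T
  b <- backsolve(ch, t(backsolve(ch, h, transpose = TRUE)), transpose = TRUE)
  b <- (b + t(b)) / 2
  eg <- eigen(b, symmetric = TRUE)
  keep <- seq_len(k)
  a <- backsolve(ch, eg$vectors[, keep, drop = FALSE])
  # scale: a' (E/df_e) a = 1 (clamped away from zero for ridge-recovered
  # null directions of a rank-deficient E)
  w <- e_eff / df_e
  sc2 <- diag(t(a) %*% w %*% a)
  sc <- sqrt(pmax(sc2, .Machine$double.eps * max(abs(sc2), 1)))
  a <- sweep(a, 2, sc, "/")
  a <- fix_signs(a)
  std <- a * sqrt(diag(w))
  rownames(a) <- rownames(std) <- rownames(e)
  colnames(a) <- colnames(std) <- paste0("CD", keep)
  list(eigenvalues = eg$values[keep], raw = a, standardized = std)
}

#' Top principal-component loadings of a symmetric matrix
#'
#' @param m symmetric covariance or correlation matrix.
#' @param k number of components (default 4).
#' @return p x k matrix of unit-norm eigenvectors ordered by algebraic
#'   eigenvalue, signs fixed so the largest-magnitude entry of each loading
#'   is positive; eigenvalues attached as attribute \code{"eigenvalues"}.
#' @export
pca_components <- function(m, k = 4) {
  m <- as.matrix(m)
  if (k > ncol(m)) stop("k exceeds the matrix dimension")
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- fix_signs(eg$vectors[, seq_len(k), drop = FALSE])
  rownames(v) <- rownames(m)
  colnames(v) <- paste0("PC", seq_len(k))
  attr(v, "eigenvalues") <- eg$values[seq_len(k)]
  v
}

#' Compute score variables from a set of loadings
#'
#' Scores are linear combinations of the (column-centered, optionally
#' scaled) CLR abundances: covariance-derived and raw-CDA loadings are
#' applied to centered values, correlation-derived and standardized-CDA
#' loadings to centered-and-scaled values.
#'
#' @param loadings named list; each element is a list with \code{loadings}
#'   (genera x components matrix) and \code{scale} (logical: use
#'   centered-and-scaled CLR values).
#' @param clr samples x genera CLR matrix; columns must match the loading
#'   rows.
#' @return samples x (source x component) score matrix with column names
#'   like \code{"HypCovPC1"}.
#' @export
score_variables <- function(loadings, clr) {
  clr <- as.matrix(clr)
  centered <- scale(clr, center = TRUE, scale = FALSE)
  scaled <- scale(clr, center = TRUE, scale = TRUE)
  cols <- lapply(names(loadings), function(src) {
    ld <- loadings[[src]]$loadings
    if (!identical(rownames(ld), colnames(clr))) {
      if (is.null(rownames(ld)) || !all(rownames(ld) %in% colnames(clr)) ||
          nrow(ld) != ncol(clr)) {
        stop("loading genera do not match CLR columns for source ", src)
      }
      ld <- ld[colnames(clr), , drop = FALSE]
    }
    x <- if (isTRUE(loadings[[src]]$scale)) scaled else centered
    sc <- x %*% ld
    colnames(sc) <- paste0(src, colnames(ld))
    sc
  })
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(clr)
  out
}

#' Construct the full set of polymicrobial score variables
#'
#' End-to-end construction of the polymicrobial traits from CLR abundances
#' of the core genera: a sequential MANOVA SSCP decomposition with genotype,
#' digestion batch and plate(batch) fixed effects; hypothesis covariance and
#' correlation matrices (genotype SSCP over its degrees of freedom); the
#' genetic covariance and correlation matrices solved from expected mean
#' squares; PCA of each of the four matrices (top \code{n_components}); and
#' canonical discriminant analysis (raw and standardized coefficients). With
#' the default four components this yields 24 score variables: 16 PCA-derived
#' (4 sources x 4 components) and 8 CDA-derived.
#'
#' @param clr samples x genera CLR abundance matrix (blank wells excluded).
#' @param genotype genotype factor per sample.
#' @param batch,plate optional nuisance factors (plate nests in batch).
#' @param n_components components retained per source (default 4).
#' @return list with \code{scores} (samples x 24 matrix), \code{loadings}
#'   (per-source list), \code{sscp} (the decomposition) and
#'   \code{genetic_cov}.
#' @export
polymicrobial_scores <- function(clr, genotype, batch = NULL, plate = NULL,
                                 n_components = 4) {
  clr <- as.matrix(clr)
  dec <- manova_sscp(clr, genotype, batch, plate)
  m_h <- sscp_to_cov(dec$H$genotype, dec$df["genotype"])
  m_e <- sscp_to_cov(dec$E, dec$df_error)
  reps <- table(droplevels(as.factor(genotype)))
  g_cov <- genetic_covariance(m_h, m_e, reps)
  cd <- cda(dec$H$genotype, dec$E, dec$df_error, k = n_components)
  colnames(cd$raw) <- colnames(cd$standardized) <- as.character(seq_len(n_components))
  loadings <- list(
    HypCov  = list(loadings = pca_components(m_h, n_components), scale = FALSE),
    HypCorr = list(loadings = pca_components(cov_to_corr(m_h), n_components), scale = TRUE),
    GenCov  = list(loadings = pca_components(g_cov, n_components), scale = FALSE),
    GenCorr = list(loadings = pca_components(cov_to_corr_safe(g_cov), n_components), scale = TRUE),
    RawCD   = list(loadings = cd$raw, scale = FALSE),
    StdCD   = list(loadings = cd$standardized, scale = TRUE)
  )
  scores <- score_variables(loadings, clr)
  list(scores = scores, loadings = loadings, sscp = dec, genetic_cov = g_cov)
}

# genetic covariance can have non-positive diagonal entries (it is a
# difference of mean squares); fall back to unit diagonal for such genera so
# the correlation-source loadings remain defined
cov_to_corr_safe <- function(v) {
  d <- diag(v)
  if (any(d <= 0)) {
    d[d <= 0] <- 1
    message("genetic covariance has non-positive diagonal entries; ",
            "affected genera left unscaled in the correlation matrix")
  }
  s <- 1 / sqrt(d)
  out <- v * tcrossprod(s)
  diag(out) <- 1
  out
}
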