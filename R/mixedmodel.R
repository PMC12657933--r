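#' Fit variance components and BLUPs by EM-REML
#'
#' Fits the trait model
#' \code{y = X beta + Z_g u_g + Z_b u_b + Z_p u_p + Z_r u_r + Z_c u_c + e}
#' with genotype effects \code{u_g ~ N(0, K sigma^2_g)} structured by a
#' kinship matrix and independent random effects for digestion batch, plate,
#' row-within-plate and column-within-plate. The kinship structure is
#' absorbed by the Cholesky transform \code{Z_g <- Z_g L}, \code{K = L L'},
#' after which all components are iid variance multiples and the standard
#' EM-REML updates on Henderson's mixed-model equations apply:
#' \deqn{\sigma^2_i \leftarrow (\hat u_i'\hat u_i + \sigma^2_e\,
#'   \mathrm{tr}(C^{ii})) / q_i, \qquad
#'   \sigma^2_e \leftarrow (y'y - \hat\theta' W'y) / (n - p).}
#' Variances are constrained nonnegative (floored at a tiny multiple of the
#' trait variance); iteration stops when the largest relative parameter
#' change falls below \code{tol} or after \code{max_iter} iterations.
#'
#' @param y numeric trait vector, one entry per design row.
#' @param design data.frame with column \code{line_id} and optionally
#'   \code{digestion_batch}, \code{plate_id}, \code{plate_row},
#'   \code{plate_column} (rows and columns are nested within plate).
#' @param K optional kinship matrix (dimnames = line ids, covering every
#'   design line); identity structure is used when \code{NULL}.
#' @param pcs optional matrix of genotype principal components (rownames =
#'   line ids) entered as fixed covariates; conventionally the first three.
#' @param random_terms which random terms to include (of those the design
#'   provides).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return object of class \code{vc_fit}: list with \code{varcomp} (named
#'   vector: genotype, [batch, plate, row, column,] residual), \code{beta}
#'   (fixed effects), \code{blup} (named genotype BLUPs on the line scale),
#'   \code{loglik} (restricted log-likelihood at the estimates),
#'   \code{loglik_trace}, \code{converged}, \code{n_iter}.
#' @export
fit_variance_components <- function(y, design, K = NULL, pcs = NULL,
                                    random_terms = c("genotype", "batch",
                                                     "plate", "row", "column"),
                                    tol = 1e-6, max_iter = 500L) {
  stopifnot(length(y) == nrow(design))
  ok <- !is.na(y)
  y <- y[ok]; design <- design[ok, , drop = FALSE]
  n <- length(y)
  lines <- design$line_id

  # fixed part: intercept + genotype PCs
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (is.null(rownames(pcs))) stop("pcs must have line ids as rownames")
    missing_pc <- setdiff(lines, rownames(pcs))
    if (length(missing_pc)) stop("pcs missing for lines: ",
                                 paste(head(missing_pc, 5), collapse = ", "))
    X <- cbind(X, pcs[lines, , drop = FALSE])
  }
  p_rank <- qr(X)$rank

  # random-effect incidence matrices
  incidence <- function(f) {
    f <- droplevels(as.factor(f))
    z <- model.matrix(~ f - 1)
    colnames(z) <- levels(f)
    z
  }
  Z <- list()
  if ("genotype" %in% random_terms) {
    lev <- if (!is.null(K)) rownames(K) else sort(unique(lines))
    if (!is.null(K) && length(setdiff(lines, lev))) {
      stop("kinship matrix does not cover all design lines")
    }
    zg <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    zg[cbind(seq_len(n), match(lines, lev))] <- 1
    L_k <- NULL
    if (!is.null(K)) {
      K <- (K + t(K)) / 2
      L_k <- t(chol(K + diag(1e-8 * mean(diag(K)), nrow(K))))
      zg <- zg %*% L_k
    }
    Z$genotype <- zg
    attr(Z$genotype, "L_k") <- L_k
    attr(Z$genotype, "levels") <- lev
  }
  if ("batch" %in% random_terms && !is.null(design$digestion_batch) &&
      length(unique(design$digestion_batch)) > 1) {
    Z$batch <- incidence(design$digestion_batch)
  }
  if ("plate" %in% random_terms && !is.null(design$plate_id) &&
      length(unique(design$plate_id)) > 1) {
    Z$plate <- incidence(design$plate_id)
  }
  if ("row" %in% random_terms && !is.null(design$plate_row) &&
      !is.null(design$plate_id)) {
    Z$row <- incidence(paste(design$plate_id, design$plate_row))
  }
  if ("column" %in% random_terms && !is.null(design$plate_column) &&
      !is.null(design$plate_id)) {
    Z$column <- incidence(paste(design$plate_id, design$plate_column))
  }
  if (!length(Z)) stop("no random terms could be formed from the design")
  if (!"genotype" %in% names(Z)) stop("a genotype random term is required")
  q_i <- vapply(Z, ncol, integer(1))
  Zall <- do.call(cbind, Z)
  W <- cbind(X, Zall)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  p <- ncol(X)
  blocks <- split(seq_len(sum(q_i)), rep(seq_along(q_i), q_i))

  v_y <- var(y)
  if (v_y == 0) stop("trait has zero variance")
  floor_v <- 1e-10 * v_y
  sig <- rep(v_y / (length(Z) + 1), length(Z))
  sig_e <- v_y / (length(Z) + 1)

  reml_ll <- function(A, sig, sig_e, theta) {
    # restricted log-likelihood from MME identities (up to a constant)
    q_tot <- sum(q_i)
    Azz <- A[(p + 1):(p + q_tot), (p + 1):(p + q_tot), drop = FALSE]
    ch_z <- chol(Azz)
    log_det_M <- 2 * sum(log(diag(ch_z))) - q_tot * log(sig_e)
    log_det_V <- n * log(sig_e) + sum(q_i * log(sig)) + log_det_M
    Xtz <- A[1:p, (p + 1):(p + q_tot), drop = FALSE]
    xvx <- (WtW[1:p, 1:p, drop = FALSE] -
              Xtz %*% chol2inv(ch_z) %*% t(Xtz)) / sig_e
    ypy <- (yty - sum(theta * Wty)) / sig_e
    ld_xvx <- determinant(xvx, logarithm = TRUE)$modulus
    -0.5 * (log_det_V + as.numeric(ld_xvx) + ypy)
  }

  converged <- FALSE
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    A <- WtW
    for (i in seq_along(Z)) {
      idx <- p + blocks[[i]]
      A[cbind(idx, idx)] <- A[cbind(idx, idx)] + sig_e / sig[i]
    }
    A_inv <- solve(A)
    theta <- drop(A_inv %*% Wty)
    u_hat <- theta[-seq_len(p)]
    sig_new <- vapply(seq_along(Z), function(i) {
      idx_u <- blocks[[i]]
      idx_a <- p + idx_u
      (sum(u_hat[idx_u]^2) + sig_e * sum(diag(A_inv)[idx_a])) / q_i[i]
    }, numeric(1))
    sig_e_new <- (yty - sum(theta * Wty)) / (n - p_rank)
    sig_new <- pmax(sig_new, floor_v)
    sig_e_new <- max(sig_e_new, floor_v)
    ll_trace <- c(ll_trace, reml_ll(A, sig, sig_e, theta))
    delta <- max(abs(c(sig_new, sig_e_new) - c(sig, sig_e)) /
                   (abs(c(sig, sig_e)) + 1e-10))
    sig <- sig_new; sig_e <- sig_e_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("EM-REML did not converge in %d iterations (last relative change %.2e)",
                    max_iter, delta), call. = FALSE)
  }

  # final solve at the estimates
  A <- WtW
  for (i in seq_along(Z)) {
    idx <- p + blocks[[i]]
    A[cbind(idx, idx)] <- A[cbind(idx, idx)] + sig_e / sig[i]
  }
  A_inv <- solve(A)
  theta <- drop(A_inv %*% Wty)
  beta <- setNames(theta[seq_len(p)], colnames(X))
  u_hat <- theta[-seq_len(p)]
  ug <- u_hat[blocks[[which(names(Z) == "genotype")]]]
  L_k <- attr(Z$genotype, "L_k")
  if (!is.null(L_k)) ug <- drop(L_k %*% ug)
  blup <- setNames(ug, attr(Z$genotype, "levels"))

  vc <- setNames(c(sig, sig_e), c(names(Z), "residual"))
  structure(
    list(varcomp = vc, beta = beta, blup = blup,
         loglik = reml_ll(A, sig, sig_e, theta),
         loglik_trace = ll_trace, converged = converged, n_iter = iter),
    class = "vc_fit"
  )
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("EM-REML variance components", if (!x$converged) "(NOT converged)", "\n")
  print(round(x$varcomp, 6))
  cat(sprintf("H2 = %.3f; logLik = %.3f; iterations = %d\n",
              broad_sense_h2(x), x$loglik, x$n_iter))
  invisible(x)
}

#' Broad-sense heritability
#'
#' The conservative ratio of the genotype variance to the total phenotypic
#' variance: genotype over genotype + all other modeled effects + residual.
#'
#' @param vc a \code{vc_fit} object or a named variance vector containing
#'   \code{"genotype"}.
#' @return H-squared in [0, 1].
#' @export
broad_sense_h2 <- function(vc) {
  v <- if (inherits(vc, "vc_fit")) vc$varcomp else vc
  if (!"genotype" %in% names(v)) stop("no genotype variance component")
  total <- sum(v)
  if (total <= 0) stop("total variance must be positive")
  unname(v["genotype"] / total)
}

#' Heritability filter for trait inclusion
#'
#' @param h2 named numeric vector of per-trait broad-sense heritabilities.
#' @param threshold inclusion threshold (default 0.1).
#' @param inclusive retain traits at exactly the threshold (default TRUE,
#'   i.e. keep H2 >= threshold).
#' @return character vector of retained trait names; removed traits and
#'   their H2 are reported in a message (empty result warns).
#' @export
heritability_filter <- function(h2, threshold = 0.1, inclusive = TRUE) {
  keep <- if (inclusive) h2 >= threshold else h2 > threshold
  removed <- h2[!keep]
  if (length(removed)) {
    message(sprintf("heritability filter removed %d trait(s): %s",
                    length(removed),
                    paste(sprintf("%s (%.3f)", names(removed), removed),
                          collapse = ", ")))
  }
  if (!any(keep)) warning("no traits pass the heritability filter", call. = FALSE)
  names(h2)[keep]
}
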