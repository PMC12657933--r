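test_that("core-genus selection takes the smallest covering prefix", {
  # mean relabs 50/30/15/5 percent: 2 genera cover 80% (<90%), 3 cover 95%
  x <- matrix(rep(c(50, 30, 15, 5), each = 4), 4,
              dimnames = list(NULL, c("g1", "g2", "g3", "g4")))
  expect_equal(select_core_genera(x, 0.90), c("g1", "g2", "g3"))
  expect_setequal(select_core_genera(x, 1.0), c("g1", "g2", "g3", "g4"))
  single <- matrix(5, 3, 1, dimnames = list(NULL, "only"))
  expect_equal(select_core_genera(single), "only")
  expect_error(select_core_genera(x, 0), "threshold")
})

test_that("sequential SSCP reproduces univariate ANOVA sums of squares", {
  toy <- toy_sscp_data()
  s <- manova_sscp(toy$y, toy$genotype)
  expect_equal(unname(s$H$genotype), matrix(16))
  expect_equal(unname(s$E), matrix(4))
  expect_equal(unname(s$df["genotype"]), 1)
  expect_equal(s$df_error, 2)
  # single genotype level -> zero hypothesis SSCP
  s1 <- manova_sscp(matrix(rnorm(4)), rep("g", 4))
  expect_equal(unname(s1$H$genotype), matrix(0))

  # multivariate case against stats::manova on a balanced orthogonal design
  set.seed(1)
  gt <- rep(sprintf("g%d", 1:4), each = 4)
  bt <- rep(c("b1", "b2"), 8)
  y <- matrix(rnorm(48), 16, 3)
  s2 <- manova_sscp(y, gt, batch = bt)
  fit <- summary(stats::manova(y ~ factor(gt) + factor(bt)))$SS
  expect_equal(unname(s2$H$genotype), unname(fit$`factor(gt)`))
  expect_equal(unname(s2$H$batch), unname(fit$`factor(bt)`))
  expect_equal(unname(s2$E), unname(fit$Residuals))
  # SSCP diagonals equal per-column ANOVA sums of squares
  a <- anova(lm(y[, 2] ~ factor(gt) + factor(bt)))
  expect_equal(s2$H$genotype[2, 2], a["factor(gt)", "Sum Sq"])
  # additivity: H terms + E = total centered SSCP
  total <- crossprod(scale(y, scale = FALSE))
  expect_equal(s2$H$genotype + s2$H$batch + s2$E, total, ignore_attr = TRUE)
  expect_error(manova_sscp(toy$y, c("a", "b", "c", "d")), "saturated")
})

test_that("SSCP/covariance/correlation conversions are exact", {
  expect_equal(sscp_to_cov(matrix(16), 1), matrix(16))
  v <- matrix(c(4, 2, 2, 9), 2)
  cr <- cov_to_corr(v)
  expect_equal(diag(cr), c(1, 1))
  expect_equal(cr[1, 2], 2 / 6)
  expect_equal(cov_to_corr(diag(c(2, 5))), diag(2))
  expect_error(sscp_to_cov(v, 0), "positive")
  expect_error(cov_to_corr(matrix(c(0, 0, 0, 1), 2)), "positive")
})

test_that("genetic covariance solves the expected-mean-square equations", {
  toy <- toy_sscp_data()
  s <- manova_sscp(toy$y, toy$genotype)
  m_h <- sscp_to_cov(s$H$genotype, s$df["genotype"])
  m_e <- sscp_to_cov(s$E, s$df_error)
  expect_equal(unname(genetic_covariance(m_h, m_e, 2)), matrix(7))
  # M_H = M_E gives the zero matrix
  expect_equal(unname(genetic_covariance(m_e, m_e, 3)), matrix(0))
  # unbalanced EMS coefficient: c = (N - sum n_i^2 / N) / (g - 1)
  expect_equal(melscan:::ems_coefficient(c(3, 3, 3)), 3)
  expect_equal(melscan:::ems_coefficient(c(2, 4)), (6 - 20 / 6) / 1)
  expect_error(genetic_covariance(m_h, m_e, 0), "positive")
})

test_that("genetic covariance recovers the realized genotypic covariance", {
  set.seed(9)
  p <- 3
  G <- matrix(c(1, .5, .2, .5, 1.2, .3, .2, .3, 0.8), 3)
  n_g <- 500; r <- 3
  gv <- matrix(rnorm(n_g * p), n_g) %*% chol(G)
  y <- gv[rep(1:n_g, each = r), ] +
    matrix(rnorm(n_g * r * p), n_g * r) %*% chol(diag(c(.5, .4, .6)))
  gt <- rep(sprintf("g%03d", 1:n_g), each = r)
  s <- manova_sscp(y, gt)
  sg <- genetic_covariance(sscp_to_cov(s$H$genotype, s$df["genotype"]),
                           sscp_to_cov(s$E, s$df_error), r)
  realized <- cov(gv)
  expect_lt(max(abs(sg - realized)) / mean(diag(realized)), 0.15)
  expect_lt(max(abs(diag(sg) - diag(G)) / diag(G)), 0.15)
})

test_that("CDA solves the generalized eigenproblem", {
  # E = identity reduces to the eigenvectors of H
  h <- matrix(c(5, 2, 2, 3), 2)
  cd <- cda(h, diag(2), df_e = 10, k = 2)
  eg <- eigen(h)
  expect_equal(abs(cor(cd$raw[, 1], eg$vectors[, 1])), 1, tolerance = 1e-10)
  expect_equal(cd$eigenvalues, eg$values)

  # 2-variable 3-group toy: leading direction matches a 3600-point grid oracle
  set.seed(2)
  g <- rep(c("a", "b", "c"), each = 4)
  y <- cbind(rnorm(12) + rep(c(0, 1, 2), each = 4),
             rnorm(12) + rep(c(0, .5, -1), each = 4))
  s <- manova_sscp(y, g)
  cd2 <- cda(s$H$genotype, s$E, s$df_error, k = 2)
  ang <- seq(0, pi, length.out = 3601)[-3601]
  ratios <- vapply(ang, function(a) {
    v <- c(cos(a), sin(a))
    drop((v %*% s$H$genotype %*% v) / (v %*% s$E %*% v))
  }, numeric(1))
  best <- ang[which.max(ratios)]
  got <- atan2(cd2$raw[2, 1], cd2$raw[1, 1]) %% pi
  expect_lt(min(abs(got - best), pi - abs(got - best)) * 180 / pi, 0.1)
  # raw coefficients normalized to unit within-group variance
  w <- s$E / s$df_error
  expect_equal(drop(t(cd2$raw[, 1]) %*% w %*% cd2$raw[, 1]), 1)
  expect_equal(cd2$standardized, cd2$raw * sqrt(diag(w)), ignore_attr = TRUE)

  # permuting variable order permutes coefficients, eigenvalues unchanged
  perm <- c(2, 1)
  cd3 <- cda(s$H$genotype[perm, perm], s$E[perm, perm], s$df_error, k = 2)
  expect_equal(cd3$eigenvalues, cd2$eigenvalues)
  expect_equal(abs(cd3$raw[perm, 1]), abs(cd2$raw[, 1]), tolerance = 1e-8)
})

test_that("CDA eigenvalues are invariant to factor-dummy recoding", {
  # recoding the design matrix leaves H and E (and hence lambda) unchanged:
  # compare reference coding vs sum-to-zero coding via direct SSCP
  set.seed(3)
  g <- rep(c("a", "b", "c"), each = 5)
  y <- matrix(rnorm(45), 15, 3)
  s <- manova_sscp(y, g)
  fit1 <- lm(y ~ C(factor(g), contr.treatment))
  fit2 <- lm(y ~ C(factor(g), contr.sum))
  h1 <- crossprod(fitted(fit1) - rep(colMeans(y), each = 15))
  h2 <- crossprod(fitted(fit2) - rep(colMeans(y), each = 15))
  expect_equal(h1, h2)
  l1 <- cda(h1, crossprod(resid(fit1)), 12, k = 3)$eigenvalues
  expect_equal(l1, cda(s$H$genotype, s$E, s$df_error, k = 3)$eigenvalues,
               tolerance = 1e-10)
})

test_that("PCA loadings are orthonormal with a fixed sign convention", {
  m <- matrix(c(2, 1, 1, 2), 2)
  out <- pca_components(m, k = 2)
  expect_equal(abs(out[, 1]), rep(1 / sqrt(2), 2))
  expect_equal(attr(out, "eigenvalues")[1], 3)
  # diagonal matrix: standard basis ordered by diagonal value
  d <- pca_components(diag(c(1, 5, 3)), k = 3)
  expect_equal(abs(d[, 1]), c(0, 1, 0))
  expect_equal(abs(d[, 2]), c(0, 0, 1))
  set.seed(4)
  a <- crossprod(matrix(rnorm(49), 7))
  v <- pca_components(a, k = 4)
  expect_equal(crossprod(v), diag(4), ignore_attr = TRUE, tolerance = 1e-10)
  # sign convention: largest-magnitude entry positive
  expect_true(all(apply(v, 2, function(x) x[which.max(abs(x))] > 0)))
  expect_error(pca_components(m, k = 3), "dimension")
})

test_that("default polymicrobial construction yields 24 scores (16 PCA + 8 CDA)", {
  set.seed(5)
  n_g <- 30; r <- 3; p <- 7
  gt <- rep(sprintf("g%02d", 1:n_g), each = r)
  batch <- rep(c("b1", "b2", "b3"), length.out = n_g * r)
  plate <- rep(c("p1", "p2"), length.out = n_g * r)
  gvals <- matrix(rnorm(n_g * p), n_g, p)
  counts <- matrix(rpois(n_g * r * p, 50), n_g * r, p) + 1
  clr <- clr_transform(counts * exp(gvals[rep(1:n_g, each = r), ] / 2))
  colnames(clr) <- paste0("Gen", 1:p)
  ps <- polymicrobial_scores(clr, gt, batch, plate)
  expect_equal(ncol(ps$scores), 24)
  expect_equal(sum(grepl("PC[1-4]$", colnames(ps$scores))), 16)
  expect_equal(sum(grepl("CD[1-4]$", colnames(ps$scores))), 8)
  expect_setequal(unique(sub("(PC|CD)[1-4]$", "", colnames(ps$scores))),
                  c("HypCov", "HypCorr", "GenCov", "GenCorr", "Raw", "Std"))
  expect_equal(nrow(ps$scores), n_g * r)
  expect_true(all(is.finite(ps$scores)))
})

test_that("score variables are the stated linear combinations", {
  set.seed(6)
  clr <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("gA", "gB", "gC")))
  unit <- matrix(c(0, 1, 0), 3, 1, dimnames = list(colnames(clr), "PC1"))
  sc <- score_variables(list(Test = list(loadings = unit, scale = FALSE)), clr)
  # unit loading on gB with a covariance source = centered CLR of gB
  expect_equal(unname(sc[, "TestPC1"]), unname(clr[, "gB"] - mean(clr[, "gB"])))
  # duplicated sample row duplicates its score
  clr2 <- rbind(clr, clr[3, , drop = FALSE])
  sc2 <- score_variables(list(Test = list(loadings = unit, scale = FALSE)), clr2)
  expect_equal(unname(sc2[11, ]), unname(sc2[3, ]))
  bad <- matrix(1, 2, 1, dimnames = list(c("x", "y"), "PC1"))
  expect_error(score_variables(list(T = list(loadings = bad, scale = FALSE)), clr),
               "match")
})
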