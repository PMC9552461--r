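test_that("PCA scores are uncorrelated and pve sums to one", {
  Y <- makePheno(30, 12, seed = 5)
  pc <- runPCA(Y)
  C <- cor(pcScores(pc))
  expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
  expect_equal(sum(pve(pc)), 1, tolerance = 1e-10)
  expect_true(all(diff(pve(pc)) <= 1e-12))
})

test_that("a rank-1 matrix concentrates all variance in one component", {
  set.seed(2)
  x <- rnorm(15)
  v <- cbind(g1 = x, g2 = 2 * x, g3 = -0.5 * x)
  rownames(v) <- sprintf("s%02d", 1:15)
  pc <- runPCA(PhenotypeMatrix(v))
  expect_equal(pve(pc)[1], 1, tolerance = 1e-10)
  expect_lt(max(pve(pc)[-1]), 1e-10)
})

test_that("wide Gaussian matrices spread variance (no spurious structure)", {
  for (seed in 1:5) {
    pc <- runPCA(makePheno(50, 200, seed = seed))
    expect_lt(max(pve(pc)), 0.2)
    expect_equal(sum(pve(pc)), 1, tolerance = 1e-10)
  }
})

test_that("pve equals the normalized eigenvalues of the feature correlation matrix", {
  Y <- makePheno(40, 20, seed = 8)
  pc <- runPCA(Y, center = TRUE, scale = TRUE)
  ev <- eigen(cor(as.matrix(Y)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pve(pc), (ev / sum(ev))[seq_along(pve(pc))], tolerance = 1e-10)
})

test_that("scores are reproducible under consistent row permutation (up to sign)", {
  Y <- makePheno(25, 10, seed = 4)
  pc1 <- runPCA(Y)
  perm <- sample(25)
  Yp <- PhenotypeMatrix(as.matrix(Y)[perm, ])
  pc2 <- runPCA(Yp)
  # the deterministic sign convention makes the match exact, not just up to sign
  expect_equal(pcScores(pc2)[order(perm), ], pcScores(pc1), tolerance = 1e-8)
  expect_equal(pcLoadings(pc2), pcLoadings(pc1), tolerance = 1e-8)
})

test_that("duplicating a feature changes pve but keeps scores uncorrelated", {
  Y <- makePheno(20, 8, seed = 6)
  v <- as.matrix(Y)
  v2 <- cbind(v, dup = v[, 1])
  colnames(v2) <- c(colnames(v), "dup")
  pc2 <- runPCA(PhenotypeMatrix(v2))
  pc1 <- runPCA(Y)
  expect_false(isTRUE(all.equal(pve(pc1), pve(pc2)[seq_along(pve(pc1))])))
  # orthogonality holds among the components carrying variance (the
  # duplicate makes the matrix rank-deficient, so the trailing component
  # is numerically degenerate)
  keep <- pve(pc2) > 1e-12
  C <- cor(pcScores(pc2)[, keep])
  expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
})

test_that("regressOut produces residuals orthogonal to the covariates", {
  Y <- makePheno(20, 5, seed = 11)
  X <- makeCov(20, 1, seed = 12)
  Yr <- regressOut(Y, X)
  res <- as.matrix(Yr)
  # oracle: naive per-column lm residuals
  for (j in 1:5) {
    oracle <- resid(lm(as.matrix(Y)[, j] ~ as.matrix(X)))
    expect_equal(unname(res[, j]), unname(oracle), tolerance = 1e-10)
  }
  xc <- scale(as.matrix(X), scale = FALSE)
  expect_lt(max(abs(crossprod(xc, res))), 1e-8)
})

test_that("regressOut handles perfect fits and empty covariate sets", {
  X <- makeCov(15, 2, seed = 13)
  v <- cbind(as.matrix(X)[, 1], rnorm(15))
  colnames(v) <- c("gX", "gN")
  rownames(v) <- sampleIDs(X)
  Yr <- regressOut(PhenotypeMatrix(v), X)
  expect_lt(max(abs(as.matrix(Yr)[, "gX"])), 1e-10)
  # empty X1: mean-centering only
  Y <- makePheno(10, 3, seed = 14)
  Yc <- regressOut(Y, NULL)
  expect_equal(as.matrix(Yc),
               scale(as.matrix(Y), scale = FALSE)[, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("rank-deficient known covariates are dropped with a warning", {
  X <- makeCov(20, 2, seed = 15)
  v <- cbind(as.matrix(X), dup = as.matrix(X)[, 1] * 2)
  expect_warning(regressOut(makePheno(20, 3, seed = 16),
                            CovariateMatrix(v)), "collinear")
})

test_that("known-covariate filtering applies the unadjusted R^2 >= 0.9 rule", {
  pcs <- makeCov(50, 3, seed = 20, role = "inferred")
  P <- as.matrix(pcs)
  set.seed(21)
  # captured exactly, captured strongly, and orthogonal-by-construction
  strong <- 0.95 * P[, 1] + 0.05 * scale(resid(lm(rnorm(50) ~ P)))
  ortho <- resid(lm(rnorm(50) ~ P))
  Xv <- cbind(exact = P[, 1], strong = as.numeric(strong),
              ortho = as.numeric(ortho))
  rownames(Xv) <- rownames(P)
  X1 <- CovariateMatrix(Xv)
  out <- filterKnownCovariates(X1, pcs, r2Threshold = 0.9)
  # oracle R^2 from lm
  r2Oracle <- suppressWarnings( # the exact-capture column is a perfect fit
    vapply(1:3, function(j) summary(lm(Xv[, j] ~ P))$r.squared, numeric(1)))
  expect_equal(unname(out$r2), r2Oracle, tolerance = 1e-10)
  expect_equal(out$r2[["exact"]], 1, tolerance = 1e-12)
  expect_gt(out$r2[["strong"]], 0.9)
  expect_lt(out$r2[["ortho"]], 1e-10)
  expect_setequal(out$dropped, c("exact", "strong"))
  expect_equal(colnames(as.matrix(out$kept)), "ortho")
})

test_that("pca_direct and pca_resid agree when there are no known covariates", {
  Y <- makePheno(30, 15, seed = 22)
  a <- inferCovariates(Y, NULL, "pca_direct", K = 4)
  b <- inferCovariates(Y, NULL, "pca_resid", K = 4)
  expect_equal(abs(as.matrix(a$inferred)), abs(as.matrix(b$inferred)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA recovers strong hidden covariates (parameter recovery)", {
  conc <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 100; p <- 200
    X2v <- rmat(n, 3, seed = seed + 100, prefix = c("sample", "hid"))
    G <- X2v %*% matrix(rnorm(3 * p), 3, p)
    v <- G + 0.3 * rmat(n, p, seed = seed + 200)
    dimnames(v) <- list(rownames(X2v), sprintf("feat%03d", seq_len(p)))
    Y <- PhenotypeMatrix(v)
    inf <- inferCovariates(Y, NULL, "pca_direct", K = 3)
    concordanceScores(CovariateMatrix(X2v, role = "hidden_truth"),
                      inf$inferred)$concordance
  }, numeric(1))
  expect_gt(min(conc), 0.9)
})

test_that("pca_resid removes a known covariate from the leading PCs", {
  set.seed(30)
  n <- 100; p <- 150
  hid <- rmat(n, 2, seed = 31, prefix = c("sample", "hid"))
  G <- hid %*% matrix(rnorm(2 * p), 2, p)
  v <- G + 0.5 * rmat(n, p, seed = 32)
  dimnames(v) <- list(rownames(hid), sprintf("feat%03d", seq_len(p)))
  Y <- PhenotypeMatrix(v)
  X1 <- CovariateMatrix(hid[, 1, drop = FALSE]) # one hidden covariate is "known"
  inf <- inferCovariates(Y, X1, "pca_resid", K = 2)
  # reverse check: the known covariate is no longer captured by the PCs
  r2 <- summary(lm(hid[, 1] ~ as.matrix(inf$inferred)))$r.squared
  expect_lt(r2, 0.05)
  # but the remaining hidden covariate still is
  r2b <- summary(lm(hid[, 2] ~ as.matrix(inf$inferred)))$r.squared
  expect_gt(r2b, 0.9)
})

test_that("K bounds are enforced", {
  Y <- makePheno(10, 4, seed = 40)
  expect_error(inferCovariates(Y, NULL, "pca_direct", K = 0), "K must be")
  expect_error(inferCovariates(Y, NULL, "pca_direct", K = 5), "K must be")
  v <- cbind(g1 = rep(1, 5), g2 = rnorm(5))
  rownames(v) <- paste0("s", 1:5)
  expect_error(runPCA(v, scale = TRUE), "zero-variance")
})
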