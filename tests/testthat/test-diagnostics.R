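# Brute-force check that a clustering satisfies the defining criterion:
# within each cluster all pairwise |cor| strictly above the threshold,
# and the clustering is the coarsest complete-linkage-consistent one.
validClustering <- function(ac, assign, threshold) {
  for (cl in unique(assign)) {
    idx <- which(assign == cl)
    if (length(idx) > 1L) {
      sub <- ac[idx, idx]
      if (any(sub[upper.tri(sub)] <= threshold)) return(FALSE)
    }
  }
  TRUE
}

test_that("identical factors collapse to one cluster at every threshold", {
  set.seed(300)
  x <- rnorm(40)
  v <- cbind(f1 = x, f2 = x, f3 = -x, f4 = 2 * x + 3)
  rownames(v) <- sprintf("s%02d", 1:40)
  for (thr in c(0.99, 0.9, 0.8)) {
    rep <- countFactorClusters(v, thr)
    expect_equal(rep@numClusters, 1L)
  }
})

test_that("orthogonal PCs stay in separate clusters", {
  pcs <- pcScores(runPCA(makePheno(40, 20, seed = 301)))[, 1:5]
  rep <- countFactorClusters(pcs, 0.8)
  expect_equal(rep@numClusters, 5L)
})

test_that("a near-duplicate pair clusters together only above its correlation", {
  set.seed(302)
  n <- 200
  f1 <- rnorm(n)
  noise <- resid(lm(rnorm(n) ~ f1))
  # tune the mix so the realized |cor| sits between 0.99 and 0.999
  f2 <- 0.995 * scale(f1) + 0.07 * scale(noise)
  f3 <- resid(lm(rnorm(n) ~ f1 + noise))
  v <- cbind(f1 = f1, f2 = as.numeric(f2), f3 = as.numeric(f3))
  rownames(v) <- sprintf("s%03d", seq_len(n))
  realized <- abs(cor(v[, 1], v[, 2]))
  expect_gt(realized, 0.99)
  ac <- abs(cor(v))
  for (thr in c(0.99, 0.8)) {
    rep <- countFactorClusters(v, thr)
    expect_equal(rep@numClusters, 2L) # {f1, f2} together, f3 apart
    expect_true(validClustering(ac, rep@assignment, thr))
    expect_equal(rep@assignment[1], rep@assignment[2])
    expect_false(rep@assignment[1] == rep@assignment[3])
  }
})

test_that("cluster counts are monotone non-increasing in looser thresholds", {
  set.seed(303)
  for (i in 1:25) {
    K <- sample(3:8, 1)
    n <- 60
    base <- matrix(rnorm(n * 2), n, 2)
    v <- vapply(seq_len(K), function(k) {
      w <- runif(1)
      as.numeric(w * base[, sample(2, 1)] + (1 - w) * rnorm(n))
    }, numeric(n))
    colnames(v) <- paste0("f", seq_len(K))
    rownames(v) <- sprintf("s%03d", seq_len(n))
    thr <- sort(runif(3, 0.1, 0.99))
    counts <- vapply(thr, function(t) countFactorClusters(v, t)@numClusters,
                     integer(1))
    expect_true(all(diff(counts) >= 0)) # tighter threshold, more clusters
  }
})

test_that("zero-variance factors are rejected", {
  v <- cbind(f1 = rep(1, 10), f2 = rnorm(10))
  rownames(v) <- sprintf("s%02d", 1:10)
  expect_error(countFactorClusters(v, 0.9), "zero-variance")
})

test_that("matching factors that are reversed PCs recovers the reversal", {
  pcs <- pcScores(runPCA(makePheno(50, 30, seed = 310)))[, 1:4]
  factors <- pcs[, 4:1]
  colnames(factors) <- paste0("factor", 1:4)
  rep <- matchFactorsToPCs(factors, pcs)
  expect_equal(rep@permutation, c(4L, 3L, 2L, 1L))
  expect_equal(rep@diagMean, 1, tolerance = 1e-10)
  expect_equal(rep@offdiagMean, 0, tolerance = 1e-10)
})

test_that("matching is invariant to sign flips of factors or PCs", {
  pcs <- pcScores(runPCA(makePheno(40, 20, seed = 311)))[, 1:3]
  factors <- pcs[, c(2, 3, 1)]
  colnames(factors) <- paste0("factor", 1:3)
  a <- matchFactorsToPCs(factors, pcs)
  factors2 <- factors; factors2[, 2] <- -factors2[, 2]
  pcs2 <- pcs; pcs2[, 1] <- -pcs2[, 1]
  b <- matchFactorsToPCs(factors2, pcs2)
  expect_identical(a@permutation, b@permutation)
  expect_equal(a@pairCor, b@pairCor, tolerance = 1e-12)
})

test_that("noise factors match PCs only weakly", {
  set.seed(312)
  means <- vapply(1:20, function(i) {
    Y <- makePheno(200, 50, seed = 320 + i)
    pcs <- pcScores(runPCA(Y))[, 1:5]
    f <- rmat(200, 5, seed = 620 + i, prefix = c("sample", "f"))
    matchFactorsToPCs(f, pcs)@diagMean
  }, numeric(1))
  expect_lt(mean(means), 0.35)
})

test_that("greedy matching is documented against the exhaustive oracle", {
  # helper to build factor sets realizing a target |cor| pattern is overkill;
  # instead check greedy == optimal when the matrix is diagonally dominant,
  # and that the two can differ on an adversarial pattern.
  adversarial <- rbind(c(0.90, 0.85, 0.10),
                       c(0.88, 0.20, 0.15),
                       c(0.30, 0.84, 0.80))
  greedyPerm <- local({
    work <- adversarial; perm <- integer(3)
    for (s in 1:3) {
      ij <- arrayInd(which.max(work), dim(work))
      perm[ij[1]] <- ij[2]
      work[ij[1], ] <- -Inf; work[, ij[2]] <- -Inf
    }
    perm
  })
  # exhaustive best bijection
  best <- NULL; bestVal <- -Inf
  for (pm in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))) {
    val <- sum(adversarial[cbind(1:3, pm)])
    if (val > bestVal) { bestVal <- val; best <- pm }
  }
  expect_equal(greedyPerm, c(1L, 3L, 2L)) # greedy takes 0.90 first
  expect_equal(best, c(2, 1, 3))          # optimal sacrifices the top cell
  expect_gt(bestVal, sum(adversarial[cbind(1:3, greedyPerm)]))

  # on real matrices with a dominant diagonal, greedy equals optimal
  pcs <- pcScores(runPCA(makePheno(60, 25, seed = 330)))[, 1:3]
  set.seed(331)
  f <- pcs + 0.2 * matrix(rnorm(180), 60, 3)
  colnames(f) <- paste0("factor", 1:3)
  g <- matchFactorsToPCs(f, pcs, method = "greedy")
  o <- matchFactorsToPCs(f, pcs, method = "optimal")
  expect_identical(g@permutation, o@permutation)
  expect_equal(g@diagMean, o@diagMean, tolerance = 1e-12)
})

test_that("the package's own PCs are self-consistent under matching", {
  Y <- makePheno(80, 40, seed = 340)
  pcs <- pcScores(runPCA(Y))
  f <- pcs[, 1:6]
  colnames(f) <- paste0("factor", 1:6)
  rep <- matchFactorsToPCs(f, pcs[, 1:6])
  expect_equal(rep@diagMean, 1, tolerance = 1e-10)
  expect_equal(rep@offdiagMean, 0, tolerance = 1e-10)
  cl <- countFactorClusters(f, 0.8)
  expect_equal(cl@numClusters, 6L)
})

test_that("matching requires at least as many PCs as factors", {
  pcs <- pcScores(runPCA(makePheno(20, 10, seed = 350)))
  f <- pcs[, 1:5]
  expect_error(matchFactorsToPCs(f, pcs[, 1:3]), "fewer PCs")
})
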