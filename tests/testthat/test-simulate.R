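test_that("genotype simulation is seed-deterministic with plausible maf", {
  a <- simulateGenotypes(100, 50, seed = 5)
  b <- simulateGenotypes(100, 50, seed = 5)
  expect_identical(dosages(a), dosages(b))
  expect_true(all(dosages(a) %in% c(0, 1, 2)))
  c2 <- simulateGenotypes(100, 50, seed = 6)
  expect_false(identical(dosages(a), dosages(c2)))
})

test_that("empirical maf tracks the target range", {
  G <- simulateGenotypes(300, 400, mafRange = c(0.1, 0.4), ldRho = 0.3, seed = 7)
  expect_true(all(mafs(G) >= 0.1 - 0.15 & mafs(G) <= 0.4 + 0.15))
})

test_that("LD control: no copying gives uncorrelated neighbors, strong copying correlates them", {
  G0 <- simulateGenotypes(200, 500, ldRho = 0, seed = 8)
  d0 <- dosages(G0)
  adj0 <- vapply(seq_len(ncol(d0) - 1L),
                 function(j) cor(d0[, j], d0[, j + 1L]), numeric(1))
  expect_lt(abs(mean(adj0)), 0.05)
  G9 <- simulateGenotypes(200, 200, ldRho = 0.9, seed = 9)
  d9 <- dosages(G9)
  adj9 <- vapply(seq_len(ncol(d9) - 1L),
                 function(j) cor(d9[, j], d9[, j + 1L]), numeric(1))
  expect_gt(median(abs(adj9)), 0.5)
})

test_that("design2 realizes the requested variance shares exactly", {
  sim <- simulateDesign2(quickParams(seed = 3))
  rp <- realizedPVE(sim)
  expect_true(all(abs(rp$pve_genotype - 0.1) < 1e-12))
  expect_true(all(abs(rp$pve_covariates - 0.4) < 1e-12))
  expect_true(all(abs(rp$pve_noise - 0.5) < 1e-12))
  # and per-gene, the per-component sample variances really are the shares
  Y <- as.matrix(simPhenotypes(sim))
  expect_equal(dim(Y), c(80L, 40L))
  tr <- truePairs(sim)
  expect_true(all(tr$type == "cis"))
  # every causal SNP lies in its gene's cis block
  cm <- cisMap(simGenotypes(sim))
  snps <- colnames(dosages(simGenotypes(sim)))
  for (i in seq_len(nrow(tr)))
    expect_true(match(tr$snp_id[i], snps) %in% cm[[tr$feature_id[i]]])
})

test_that("design2 is seed-deterministic and seeds differ", {
  a <- simulateDesign2(quickParams(seed = 11))
  b <- simulateDesign2(quickParams(seed = 11))
  expect_identical(as.matrix(simPhenotypes(a)), as.matrix(simPhenotypes(b)))
  expect_identical(truePairs(a), truePairs(b))
  c2 <- simulateDesign2(quickParams(seed = 12))
  expect_false(identical(as.matrix(simPhenotypes(a)), as.matrix(simPhenotypes(c2))))
})

test_that("a zero genotype share produces null QTL p-values", {
  sim <- simulateDesign2(quickParams(seed = 13, PVEGenotype = 0))
  res <- mapQTL(simPhenotypes(sim), simGenotypes(sim),
                knownCovariates(sim), scope = "cis")
  pv <- qtlTable(res)$p_value
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.07)
  # truth rows still exist, with zero realized effect
  expect_true(all(truePairs(sim)$effect == 0))
})

test_that("design1 trans hotspots pervade the transcriptome", {
  p <- simParams(design = "design1", n = 150, p = 60, snpsPerGene = 5,
                 numOfCovariates = 2, K1 = 1, PVEGenotype = 0.05,
                 PVECovariates = 0.1, pveTrans = 0.6, numFactors = 4,
                 numTransHotspots = 2, pveHotspot = 0.6, seed = 21)
  sim <- simulateDesign1(p)
  tr <- truePairs(sim)
  expect_setequal(unique(tr$type), c("cis", "trans"))
  hot <- unique(tr$snp_id[tr$type == "trans"])
  expect_length(hot, 2L)
  # a hotspot SNP associates with a large fraction of genes
  res <- mapQTL(simPhenotypes(sim), simGenotypes(sim), NULL, "all_pairs")
  tab <- qtlTable(res)
  frac <- mean(tab$p_value[tab$snp_id == hot[1]] < 0.01)
  expect_gt(frac, 0.3)
})

test_that("design1 without trans structure degenerates to a cis-only dataset", {
  p <- simParams(design = "design1", n = 60, p = 20, snpsPerGene = 4,
                 numOfCovariates = 2, K1 = 0, PVEGenotype = 0.1,
                 PVECovariates = 0.3, pveTrans = 0, numTransHotspots = 0,
                 seed = 22)
  sim <- simulateDesign1(p)
  expect_true(all(truePairs(sim)$type == "cis"))
  rp <- realizedPVE(sim)
  expect_true(all(abs(rp$pve_trans) < 1e-12))
  b <- simulateDesign1(p)
  expect_identical(as.matrix(simPhenotypes(sim)), as.matrix(simPhenotypes(b)))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(simParams(PVEGenotype = 0.6, PVECovariates = 0.5), "< 1")
  expect_error(simParams(numOfEffectSNPs = 9, snpsPerGene = 8), "numOfEffectSNPs")
  expect_error(simParams(K1 = 5, numOfCovariates = 3), "K1")
  expect_error(simParams(design = "design1", PVEGenotype = 0.3,
                         PVECovariates = 0.2, pveTrans = 0.6), "pveTrans")
  expect_error(simParams(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simulateGenotypes(10, 5, ldRho = 1), "ldRho")
})

test_that("benchmark bookkeeping: grid size, determinism, early method check", {
  base <- quickParams()
  expect_error(benchmarkGrid(base, methods = c("ideal", "bogus"), seed = 1),
               "unknown method")
  grid <- list(PVECovariates = c(0.2, 0.5))
  res <- benchmarkGrid(base, grid = grid, replicates = 2,
                       methods = c("ideal", "unadjusted", "pca_direct"),
                       seed = 4)
  expect_equal(nrow(res), 2 * 2 * 3) # cells x replicates x methods
  res2 <- benchmarkGrid(base, grid = grid, replicates = 2,
                        methods = c("ideal", "unadjusted", "pca_direct"),
                        seed = 4)
  expect_identical(res$auprc, res2$auprc)
  # the ordering the benchmark exists to detect, in the confounded cell
  confounded <- res[res$PVECovariates == 0.5, ]
  mIdeal <- mean(confounded$auprc[confounded$method == "ideal"])
  mUnadj <- mean(confounded$auprc[confounded$method == "unadjusted"])
  expect_gt(mIdeal, mUnadj)
  # inferred-covariate methods carry concordance; oracle methods do not
  expect_true(all(is.na(res$concordance[res$method == "ideal"])))
  expect_true(all(!is.na(res$concordance[res$method == "pca_direct"])))
})

test_that("hcp in the benchmark requires known covariates", {
  base <- simParams(n = 50, p = 10, snpsPerGene = 4, numOfCovariates = 2,
                    K1 = 0, seed = 5)
  expect_error(benchmarkGrid(base, methods = "hcp", seed = 1), "K1")
})
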