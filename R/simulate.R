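# Synthetic QTL data generation. Two designs: a trans-dominated factor
# design (design1) and a cis-focused design with exact control of the
# genotype and covariate variance shares (design2). All randomness flows
# from a single master seed via labeled stream splitting (deriveSeed).

#' Simulation parameters
#'
#' Builds and validates the parameter list for [simulateDesign1()] /
#' [simulateDesign2()]. Variance shares are controlled exactly: per gene,
#' the genetic, covariate (and trans) components are rescaled so their
#' realized sample-variance shares equal the requested proportions, with
#' the remainder left to i.i.d. Gaussian noise.
#'
#' Defaults describe a moderately confounded cis-QTL study: 200 samples,
#' 500 genes with 50 cis SNPs each, one causal cis SNP per gene, three
#' hidden covariates (no known ones), genotype share 0.1, covariate share
#' 0.4, minor-allele frequencies uniform on (0.05, 0.5) and mild local LD.
#'
#' @param design "design1" (trans-dominated) or "design2" (cis-focused)
#' @param n samples
#' @param p genes
#' @param snpsPerGene cis SNPs per gene (q)
#' @param numOfEffectSNPs causal cis SNPs per gene (<= snpsPerGene)
#' @param numOfCovariates total simulated covariates (known + hidden)
#' @param K1 number of covariates labeled known (first K1 columns)
#' @param PVEGenotype cis-genotype variance share per gene, in [0, 1)
#' @param PVECovariates covariate variance share per gene, in [0, 1)
#' @param mafRange minor-allele frequency range, subset of (0, 0.5]
#' @param ldRho neighbor-copying probability of the haplotype chain, [0, 1)
#' @param numFactors design1: number of latent trans factors
#' @param numTransHotspots design1: hotspot SNPs, one per factor
#'   (<= numFactors)
#' @param pveTrans design1: aggregate trans variance share per gene
#' @param pveHotspot design1: fraction of a hotspot factor's variance
#'   driven by its SNP
#' @param seed master seed
#' @return a validated parameter list (class "simParams")
#' @export
simParams <- function(design = c("design2", "design1"), n = 200L, p = 500L,
                      snpsPerGene = 50L, numOfEffectSNPs = 1L,
                      numOfCovariates = 3L, K1 = 0L, PVEGenotype = 0.1,
                      PVECovariates = 0.4, mafRange = c(0.05, 0.5),
                      ldRho = 0.3, numFactors = 10L, numTransHotspots = 5L,
                      pveTrans = 0.6, pveHotspot = 0.5, seed = 1L) {
  design <- match.arg(design)
  stopifnot(n >= 4L, p >= 1L, snpsPerGene >= 1L)
  if (numOfEffectSNPs < 1L || numOfEffectSNPs > snpsPerGene)
    stop("numOfEffectSNPs must be in [1, snpsPerGene]")
  if (K1 < 0L || K1 > numOfCovariates) stop("K1 must be in [0, numOfCovariates]")
  if (PVEGenotype < 0 || PVECovariates < 0)
    stop("variance shares must be non-negative")
  if (design == "design2" && PVEGenotype + PVECovariates >= 1)
    stop("PVEGenotype + PVECovariates must be < 1")
  if (design == "design1") {
    if (pveTrans < 0 || PVEGenotype + PVECovariates + pveTrans >= 1)
      stop("PVEGenotype + PVECovariates + pveTrans must be < 1")
    if (numTransHotspots > numFactors)
      stop("numTransHotspots must be <= numFactors")
    if (pveHotspot < 0 || pveHotspot >= 1) stop("pveHotspot must be in [0, 1)")
  }
  if (mafRange[1L] <= 0 || mafRange[2L] > 0.5 || mafRange[1L] > mafRange[2L])
    stop("mafRange must be within (0, 0.5]")
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must be in [0, 1)")
  structure(list(design = design, n = as.integer(n), p = as.integer(p),
                 snpsPerGene = as.integer(snpsPerGene),
                 numOfEffectSNPs = as.integer(numOfEffectSNPs),
                 numOfCovariates = as.integer(numOfCovariates),
                 K1 = as.integer(K1), PVEGenotype = PVEGenotype,
                 PVECovariates = PVECovariates, mafRange = mafRange,
                 ldRho = ldRho, numFactors = as.integer(numFactors),
                 numTransHotspots = as.integer(numTransHotspots),
                 pveTrans = pveTrans, pveHotspot = pveHotspot,
                 seed = as.integer(seed)),
            class = "simParams")
}

#' Simulate genotype dosages with MAF and LD structure
#'
#' Per-SNP minor-allele frequencies are drawn uniformly from `mafRange`.
#' Haplotypes follow a first-order Markov copying chain along the SNP
#' index: each allele copies its left neighbor with probability `ldRho`
#' and is otherwise a fresh Bernoulli(maf) draw, giving adjacent-SNP
#' correlation of about `ldRho` while preserving marginal frequencies
#' approximately. Dosage is the sum of two independent haplotypes.
#'
#' @param n samples
#' @param totalSnps SNP count
#' @param mafRange target frequency range, subset of (0, 0.5]
#' @param ldRho neighbor-copying probability in [0, 1)
#' @param seed RNG seed
#' @param chrom chromosome label for the coordinates
#' @param posStep base-pair spacing between adjacent SNPs
#' @return a \linkS4class{GenotypeData} (no cis map; positions are
#'   `posStep` apart on one chromosome)
#' @export
simulateGenotypes <- function(n, totalSnps, mafRange = c(0.05, 0.5),
                              ldRho = 0, seed = 1L, chrom = "chr1",
                              posStep = 1000L) {
  stopifnot(n >= 2L, totalSnps >= 1L)
  if (mafRange[1L] <= 0 || mafRange[2L] > 0.5) stop("mafRange must be within (0, 0.5]")
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must be in [0, 1)")
  set.seed(seed)
  maf <- stats::runif(totalSnps, mafRange[1L], mafRange[2L])
  H <- matrix(0, nrow = 2L * n, ncol = totalSnps)
  H[, 1L] <- stats::rbinom(2L * n, 1L, maf[1L])
  if (totalSnps > 1L) {
    for (m in 2:totalSnps) {
      h <- stats::rbinom(2L * n, 1L, maf[m])
      if (ldRho > 0) {
        copy <- stats::runif(2L * n) < ldRho
        h[copy] <- H[copy, m - 1L]
      }
      H[, m] <- h
    }
  }
  dos <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  rownames(dos) <- sprintf("sample%03d", seq_len(n))
  colnames(dos) <- sprintf("snp%05d", seq_len(totalSnps))
  coords <- data.frame(snp_id = colnames(dos), chrom = chrom,
                       pos = seq_len(totalSnps) * posStep,
                       stringsAsFactors = FALSE)
  GenotypeData(dos, snpCoords = coords)
}

# Scale a component vector to an exact sample variance. A zero target
# returns exact zeros; scaling a zero-variance vector to positive variance
# is an error (callers avoid it by construction).
.scaleToVar <- function(x, targetVar) {
  if (targetVar == 0) return(numeric(length(x)) )
  s <- stats::sd(x)
  if (s < .Machine$double.eps) stop("cannot scale a constant component to positive variance")
  x * sqrt(targetVar) / s
}

# Shared scaffolding: genotypes with per-gene cis blocks, covariates with
# the known/hidden split, ids.
.simScaffold <- function(params, extraSnps = 0L) {
  n <- params$n; p <- params$p; q <- params$snpsPerGene
  G0 <- simulateGenotypes(n, p * q + extraSnps, mafRange = params$mafRange,
                          ldRho = params$ldRho,
                          seed = deriveSeed(params$seed, "genotypes"))
  genes <- sprintf("gene%04d", seq_len(p))
  cis <- stats::setNames(lapply(seq_len(p), function(j) ((j - 1L) * q + 1L):(j * q)),
                         genes)
  G <- new("GenotypeData", dosages = dosages(G0), snpCoords = snpCoords(G0),
           maf = mafs(G0), cisMap = cis)
  set.seed(deriveSeed(params$seed, "covariates"))
  nc <- params$numOfCovariates
  X <- matrix(stats::rnorm(n * nc), nrow = n,
              dimnames = list(sampleIDs(G), if (nc) sprintf("cov%02d", seq_len(nc))))
  k1 <- params$K1
  X1 <- new("CovariateMatrix", values = X[, seq_len(k1), drop = FALSE], role = "known")
  X2 <- new("CovariateMatrix", values = X[, setdiff(seq_len(nc), seq_len(k1)), drop = FALSE],
            role = "hidden_truth")
  list(G = G, X = X, X1 = X1, X2 = X2, genes = genes, cis = cis)
}

# Gene coordinates at the center of each cis block so readGenotypes-style
# cis windows would reproduce the block structure.
.simFeatureCoords <- function(genes, cis, snpCoords) {
  mid <- vapply(cis, function(ix) snpCoords$pos[ix[ceiling(length(ix) / 2)]],
                numeric(1L))
  data.frame(feature_id = genes, chrom = snpCoords$chrom[1L],
             start = as.integer(mid), end = as.integer(mid),
             stringsAsFactors = FALSE)
}

#' Simulate a cis-focused QTL dataset (design 2)
#'
#' Per gene: `numOfEffectSNPs` causal SNPs are chosen uniformly from the
#' gene's cis block (among SNPs polymorphic in sample), cis effect sizes
#' and covariate loadings are standard normal, covariate values are shared
#' across genes, and the genetic, covariate and noise components are
#' rescaled so their realized sample-variance shares are exactly
#' PVEGenotype : PVECovariates : remainder. Gene expression is the sum of
#' the rescaled components.
#'
#' @param params a [simParams()] list with design = "design2"
#' @return a \linkS4class{SimulatedQTLData}
#' @export
simulateDesign2 <- function(params) {
  stopifnot(inherits(params, "simParams"))
  if (params$design != "design2") stop("params$design must be 'design2'")
  sc <- .simScaffold(params)
  n <- params$n; p <- params$p
  dos <- dosages(sc$G)
  pveG <- params$PVEGenotype; pveC <- params$PVECovariates
  pveE <- 1 - pveG - pveC
  set.seed(deriveSeed(params$seed, "effects"))
  Y <- matrix(NA_real_, nrow = n, ncol = p,
              dimnames = list(sampleIDs(sc$G), sc$genes))
  truth <- vector("list", p)
  realized <- matrix(NA_real_, nrow = p, ncol = 3L,
                     dimnames = list(sc$genes, c("pve_genotype", "pve_covariates", "pve_noise")))
  snpVar <- .colVars(dos)
  for (j in seq_len(p)) {
    block <- sc$cis[[j]]
    poly <- block[snpVar[block] > 0]
    if (length(poly) < params$numOfEffectSNPs)
      stop("gene ", sc$genes[j], ": not enough polymorphic cis SNPs for the requested causal count")
    causal <- sort(sample(poly, params$numOfEffectSNPs))
    beta <- stats::rnorm(params$numOfEffectSNPs)
    g <- dos[, causal, drop = FALSE] %*% beta
    gamma <- stats::rnorm(params$numOfCovariates)
    cvt <- if (params$numOfCovariates) sc$X %*% gamma else numeric(n)
    eps <- stats::rnorm(n)
    gs <- .scaleToVar(g, pveG)
    cs <- if (params$numOfCovariates) .scaleToVar(cvt, pveC) else numeric(n)
    es <- .scaleToVar(eps, pveE)
    Y[, j] <- gs + cs + es
    tot <- pveG + (if (params$numOfCovariates) pveC else 0) + pveE
    realized[j, ] <- c(pveG, if (params$numOfCovariates) pveC else 0, pveE) / tot
    scaleFac <- if (pveG > 0) sqrt(pveG) / stats::sd(g) else 0
    truth[[j]] <- data.frame(feature_id = sc$genes[j],
                             snp_id = colnames(dos)[causal],
                             effect = beta * scaleFac, type = "cis",
                             stringsAsFactors = FALSE)
  }
  coords <- .simFeatureCoords(sc$genes, sc$cis, snpCoords(sc$G))
  new("SimulatedQTLData",
      Y = PhenotypeMatrix(Y, featureCoords = coords), G = sc$G,
      X1 = sc$X1, X2 = sc$X2, truth = do.call(rbind, truth),
      realizedPVE = as.data.frame(realized), params = unclass(params))
}

#' Simulate a trans-dominated QTL dataset (design 1)
#'
#' Latent factors drive dense trans effects on all genes: `numFactors`
#' standard-normal factors, of which the first `numTransHotspots` are made
#' partially genetic by mixing in a hotspot SNP's standardized dosage with
#' weight `pveHotspot`. Each gene receives a dense factor loading (trans
#' component with aggregate share `pveTrans`), one causal cis SNP, a
#' covariate component, and noise; the four components are rescaled to
#' exact variance shares as in design 2. Ground truth records the cis
#' pairs and every (gene, hotspot SNP) pair as trans.
#'
#' With `numTransHotspots = 0` and `pveTrans = 0` the dataset degenerates
#' to a design2-like cis-only dataset (truth then contains only cis
#' pairs).
#'
#' @param params a [simParams()] list with design = "design1"
#' @return a \linkS4class{SimulatedQTLData}
#' @export
simulateDesign1 <- function(params) {
  stopifnot(inherits(params, "simParams"))
  if (params$design != "design1") stop("params$design must be 'design1'")
  sc <- .simScaffold(params, extraSnps = params$numTransHotspots)
  n <- params$n; p <- params$p
  dos <- dosages(sc$G)
  nHot <- params$numTransHotspots
  hotIdx <- if (nHot) (ncol(dos) - nHot + 1L):ncol(dos) else integer(0)
  pveG <- params$PVEGenotype; pveC <- params$PVECovariates
  pveT <- params$pveTrans
  pveE <- 1 - pveG - pveC - pveT
  set.seed(deriveSeed(params$seed, "factors"))
  Fm <- matrix(stats::rnorm(n * params$numFactors), nrow = n)
  for (h in seq_len(nHot)) {
    d <- dos[, hotIdx[h]]
    if (stats::sd(d) < .Machine$double.eps)
      stop("hotspot SNP is monomorphic in sample; increase n or mafRange")
    Fm[, h] <- sqrt(params$pveHotspot) * as.numeric(scale(d)) +
      sqrt(1 - params$pveHotspot) * stats::rnorm(n)
  }
  set.seed(deriveSeed(params$seed, "effects"))
  Y <- matrix(NA_real_, nrow = n, ncol = p,
              dimnames = list(sampleIDs(sc$G), sc$genes))
  truthCis <- vector("list", p)
  realized <- matrix(NA_real_, nrow = p, ncol = 4L,
                     dimnames = list(sc$genes,
                                     c("pve_genotype", "pve_covariates",
                                       "pve_trans", "pve_noise")))
  snpVar <- .colVars(dos)
  for (j in seq_len(p)) {
    block <- sc$cis[[j]]
    poly <- block[snpVar[block] > 0]
    if (!length(poly)) stop("gene ", sc$genes[j], ": all cis SNPs monomorphic")
    causal <- sample(poly, 1L)
    beta <- stats::rnorm(1L)
    g <- dos[, causal] * beta
    lam <- stats::rnorm(params$numFactors)
    tr <- if (pveT > 0) as.numeric(Fm %*% lam) else numeric(n)
    gamma <- stats::rnorm(params$numOfCovariates)
    cvt <- if (params$numOfCovariates) sc$X %*% gamma else numeric(n)
    eps <- stats::rnorm(n)
    gs <- .scaleToVar(g, pveG)
    ts <- .scaleToVar(tr, pveT)
    cs <- if (params$numOfCovariates) .scaleToVar(cvt, pveC) else numeric(n)
    es <- .scaleToVar(eps, pveE)
    Y[, j] <- gs + ts + cs + es
    tot <- pveG + (if (params$numOfCovariates) pveC else 0) + pveT + pveE
    realized[j, ] <- c(pveG, if (params$numOfCovariates) pveC else 0, pveT, pveE) / tot
    scaleFac <- if (pveG > 0) sqrt(pveG) / stats::sd(g) else 0
    truthCis[[j]] <- data.frame(feature_id = sc$genes[j],
                                snp_id = colnames(dos)[causal],
                                effect = beta * scaleFac, type = "cis",
                                stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truthCis)
  if (nHot && pveT > 0) {
    truthTrans <- expand.grid(feature_id = sc$genes,
                              snp_id = colnames(dos)[hotIdx],
                              stringsAsFactors = FALSE)
    truthTrans$effect <- NA_real_
    truthTrans$type <- "trans"
    truth <- rbind(truth, truthTrans)
  }
  coords <- .simFeatureCoords(sc$genes, sc$cis, snpCoords(sc$G))
  new("SimulatedQTLData",
      Y = PhenotypeMatrix(Y, featureCoords = coords), G = sc$G,
      X1 = sc$X1, X2 = sc$X2, truth = truth,
      realizedPVE = as.data.frame(realized), params = unclass(params))
}

#' Simulate under either design
#' @param params a [simParams()] list
#' @return a \linkS4class{SimulatedQTLData}
#' @export
simulateQTLData <- function(params) {
  if (params$design == "design2") simulateDesign2(params) else simulateDesign1(params)
}
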