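# Fixtures built in code: random matrices, spiked low-rank phenotype
# matrices, tiny on-disk files, and independent oracles used across tests.

rmat <- function(n, p, seed, prefix = c("sample", "feat")) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("%s%03d", prefix[1L], seq_len(n)),
                              sprintf("%s%03d", prefix[2L], seq_len(p))))
  m
}

makePheno <- function(n, p, seed = 1) PhenotypeMatrix(rmat(n, p, seed))

makeCov <- function(n, k, seed = 1, role = "known") {
  CovariateMatrix(rmat(n, k, seed, prefix = c("sample", "cov")), role = role)
}

# Low-rank "spiked" phenotype matrix: each of `nspikes` factors explains
# exactly `spikeShare` of every feature's variance, noise takes the rest.
spikedPheno <- function(n, p, nspikes, spikeShare, seed = 1) {
  set.seed(seed)
  U <- matrix(rnorm(n * nspikes), n, nspikes)
  Y <- matrix(0, n, p)
  noiseShare <- 1 - nspikes * spikeShare
  stopifnot(noiseShare > 0)
  for (j in seq_len(p)) {
    w <- rnorm(nspikes)
    comp <- sweep(U, 2L, w, "*")
    y <- 0
    for (i in seq_len(nspikes)) {
      ci <- comp[, i]
      y <- y + ci * sqrt(spikeShare) / sd(ci)
    }
    e <- rnorm(n)
    Y[, j] <- y + e * sqrt(noiseShare) / sd(e)
  }
  dimnames(Y) <- list(sprintf("sample%03d", seq_len(n)),
                      sprintf("feat%03d", seq_len(p)))
  PhenotypeMatrix(Y)
}

# Build a QTLResultTable directly from p-values (BH q over finite p),
# for metric tests that do not need the regression engine.
tableFromP <- function(p, features = NULL, snps = NULL) {
  m <- length(p)
  if (is.null(features)) features <- sprintf("g%03d", seq_len(m))
  if (is.null(snps)) snps <- sprintf("s%03d", seq_len(m))
  q <- rep(NA_real_, m)
  fin <- !is.na(p)
  q[fin] <- p.adjust(p[fin], method = "BH")
  new("QTLResultTable",
      table = data.frame(feature_id = features, snp_id = snps,
                         beta = 0, se = 1, t_stat = 0, p_value = p,
                         q_value = q, stringsAsFactors = FALSE),
      metadata = list(n = NA_integer_, df = NA_integer_))
}

# Independent AUPRC oracle: exhaustive enumeration of thresholds, with
# precision and recall recomputed from scratch at each unique p-value.
auprcOracle <- function(p, isPos) {
  o <- order(p)
  p <- p[o]; isPos <- isPos[o]
  npos <- sum(isPos)
  thr <- unique(p)
  area <- 0
  prevRec <- 0
  for (t in thr) {
    called <- p <= t
    prec <- sum(isPos & called) / sum(called)
    rec <- sum(isPos & called) / npos
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}

# Independent BH oracle: the classic step-up rule on sorted p-values.
bhRejectOracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Write a tiny diploid VCF; gts is a variants x samples character matrix.
writeTinyVCF <- function(path, gts, chrom = "chr1", pos = NULL, ids = NULL) {
  nv <- nrow(gts); ns <- ncol(gts)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(ids)) ids <- sprintf("var%02d", seq_len(nv))
  samples <- colnames(gts)
  if (is.null(samples)) samples <- sprintf("sample%03d", seq_len(ns))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nv), function(i) {
    paste(c(chrom, pos[i], ids[i], "A", "G", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  path
}

# Principal angle (radians) between the column spans of two matrices.
principalAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}

# Small deterministic design2-style parameter set for quick tests.
quickParams <- function(seed = 1, ...) {
  simParams(design = "design2", n = 80, p = 40, snpsPerGene = 8,
            numOfCovariates = 3, K1 = 1, seed = seed, ...)
}
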