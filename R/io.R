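# Readers and writers for the plain-text formats the package consumes:
# TSV matrices, GTEx-dialect phenotype BED (0-based starts on disk,
# 1-based internally), and VCF genotypes (GT field).

#' Read a molecular phenotype matrix
#'
#' TSV input is a tab-delimited matrix with a header row and row ids in
#' the first column; `orientation` says which way it is stored on disk.
#' BED input follows the GTEx phenotype dialect: columns chr, start
#' (0-based), end, feature id, then one column per sample. Either way the
#' returned matrix is oriented samples x features.
#'
#' @param path input file.
#' @param format "tsv" or "bed".
#' @param orientation for TSV: "samples_by_features" (rows are samples) or
#'   "features_by_samples".
#' @param imputeMean replace missing cells by the feature mean instead of
#'   failing.
#' @return a \linkS4class{PhenotypeMatrix}
#' @export
readPhenotypes <- function(path, format = c("tsv", "bed"),
                           orientation = c("samples_by_features", "features_by_samples"),
                           imputeMean = FALSE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "")
  coords <- NULL
  if (format == "bed") {
    if (ncol(df) < 5L) stop("phenotype BED needs 4 annotation columns plus samples")
    coords <- data.frame(feature_id = as.character(df[[4L]]),
                         chrom = as.character(df[[1L]]),
                         start = as.integer(df[[2L]]) + 1L, # 0-based on disk
                         end = as.integer(df[[3L]]),
                         stringsAsFactors = FALSE)
    vals <- t(as.matrix(df[, -(1:4), drop = FALSE]))
    colnames(vals) <- coords$feature_id
  } else {
    # data.frame subsetting silently uniquifies duplicated header names;
    # take column names from the raw header line instead
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    vals <- as.matrix(df[, -1L, drop = FALSE])
    colnames(vals) <- hdr[-1L]
    rownames(vals) <- as.character(df[[1L]])
    if (orientation == "features_by_samples") vals <- t(vals)
  }
  storage.mode(vals) <- "double"
  if (anyDuplicated(colnames(vals)))
    stop("duplicated feature ids in ", path)
  if (anyNA(vals)) {
    if (!imputeMean)
      stop("missing values in phenotype matrix (set imputeMean = TRUE to impute)")
    for (j in which(colSums(is.na(vals)) > 0L)) {
      m <- mean(vals[, j], na.rm = TRUE)
      vals[is.na(vals[, j]), j] <- m
    }
  }
  PhenotypeMatrix(vals, featureCoords = coords)
}

#' Read a covariate matrix from TSV
#'
#' Tab-delimited with a header; first column holds sample ids, remaining
#' columns are numeric covariates (categorical covariates must arrive
#' pre-encoded).
#'
#' @param path input file.
#' @param role covariate role recorded on the object.
#' @return a \linkS4class{CovariateMatrix}
#' @export
readCovariates <- function(path, role = c("known", "hidden_truth", "inferred")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  vals <- df[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1L))))
    stop("non-numeric covariate column(s): ",
         paste(names(vals)[!vapply(vals, is.numeric, logical(1L))], collapse = ", "))
  vals <- as.matrix(vals)
  rownames(vals) <- as.character(df[[1L]])
  CovariateMatrix(vals, role = role)
}

# GT string -> alternate-allele count; NA for missing; error on ploidy != 2.
.gtToDosage <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  parts <- strsplit(gt, "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(n_alleles != 2L))
    stop("non-diploid genotype call(s) encountered (ploidy != 2)")
  vapply(parts, function(a) {
    if (any(a == ".")) return(NA_real_)
    sum(a != "0")
  }, numeric(1L))
}

#' Read genotypes into a dosage matrix with a cis map
#'
#' VCF input uses the GT field: dosage is the alternate-allele count,
#' missing calls are imputed to the per-SNP mean, multi-allelic sites are
#' dropped. TSV input has columns snp_id, chrom, pos, then one column per
#' sample. SNPs with folded minor-allele frequency below `mafThreshold`
#' are dropped. When `featureCoords` is given, each feature gets the SNPs
#' within +/- `cisWindow` bp of its start (inclusive at the boundary).
#'
#' @param path input file.
#' @param format "vcf" or "tsv".
#' @param cisWindow cis-window half-width in bp (default 1e6, GTEx
#'   convention, measured from the feature start).
#' @param featureCoords data.frame (feature_id, chrom, start, end) or NULL.
#' @param samples optional sample ids the genotypes must cover; a mismatch
#'   is an error listing the offenders.
#' @param mafThreshold drop SNPs with maf below this (default 0.01).
#' @return a \linkS4class{GenotypeData}
#' @export
readGenotypes <- function(path, format = c("vcf", "tsv"), cisWindow = 1e6,
                          featureCoords = NULL, samples = NULL,
                          mafThreshold = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- VariantAnnotation::alt(vcf)
    biallelic <- lengths(alt) <= 1L
    gt <- gt[biallelic, , drop = FALSE]
    chrom <- as.character(GenomicRanges::seqnames(rr))[biallelic]
    pos <- GenomicRanges::start(rr)[biallelic]
    ids <- rownames(gt)
    dos <- t(apply(gt, 1L, .gtToDosage)) # variants x samples
    if (ncol(gt) == 1L) dos <- matrix(dos, ncol = 1L)
    dosages <- t(dos) # samples x variants
    rownames(dosages) <- colnames(gt)
    colnames(dosages) <- ids
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(df))) stop("genotype TSV needs columns snp_id, chrom, pos")
    ids <- as.character(df$snp_id)
    chrom <- as.character(df$chrom)
    pos <- as.integer(df$pos)
    dosages <- t(as.matrix(df[, setdiff(names(df), need), drop = FALSE]))
    colnames(dosages) <- ids
    storage.mode(dosages) <- "double"
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, rownames(dosages))
    if (length(missing_s))
      stop("genotype samples do not cover the phenotype samples; missing: ",
           paste(utils::head(missing_s, 10L), collapse = ", "))
    dosages <- dosages[samples, , drop = FALSE]
  }
  # mean-impute missing calls per SNP
  if (anyNA(dosages)) {
    for (j in which(colSums(is.na(dosages)) > 0L)) {
      m <- mean(dosages[, j], na.rm = TRUE)
      if (is.nan(m)) m <- 0
      dosages[is.na(dosages[, j]), j] <- m
    }
  }
  af <- colMeans(dosages) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= mafThreshold
  if (!any(keep)) stop("no SNPs pass the maf threshold")
  dosages <- dosages[, keep, drop = FALSE]
  coords <- data.frame(snp_id = ids[keep], chrom = chrom[keep], pos = pos[keep],
                       stringsAsFactors = FALSE)
  cis <- list()
  if (!is.null(featureCoords)) {
    for (i in seq_len(nrow(featureCoords))) {
      fid <- featureCoords$feature_id[i]
      hit <- which(coords$chrom == featureCoords$chrom[i] &
                     abs(coords$pos - featureCoords$start[i]) <= cisWindow)
      cis[[fid]] <- hit
    }
  }
  GenotypeData(dosages, snpCoords = coords, maf = maf[keep], cisMap = cis)
}

#' Write a phenotype matrix as TSV
#'
#' Samples in rows, features in columns, full double precision (survives a
#' read/write round trip).
#'
#' @param Y a \linkS4class{PhenotypeMatrix}
#' @param path output file
#' @export
writePhenotypes <- function(Y, path) {
  stopifnot(is(Y, "PhenotypeMatrix"))
  .writeMatrixTSV(as.matrix(Y), path, idCol = "sample_id")
}

#' Write a covariate matrix as TSV
#' @param X a \linkS4class{CovariateMatrix}
#' @param path output file
#' @export
writeCovariates <- function(X, path) {
  stopifnot(is(X, "CovariateMatrix"))
  .writeMatrixTSV(as.matrix(X), path, idCol = "sample_id")
}

#' Write genotype dosages as TSV
#'
#' Columns snp_id, chrom, pos, then one column per sample — the TSV
#' dialect `readGenotypes` accepts.
#'
#' @param G a \linkS4class{GenotypeData}
#' @param path output file
#' @export
writeGenotypes <- function(G, path) {
  stopifnot(is(G, "GenotypeData"))
  d <- dosages(G)
  co <- snpCoords(G)
  out <- cbind(co, as.data.frame(t(d), check.names = FALSE))
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QTL result table as TSV
#' @param res a \linkS4class{QTLResultTable}
#' @param path output file
#' @export
writeQTLResults <- function(res, path) {
  stopifnot(is(res, "QTLResultTable"))
  utils::write.table(qtlTable(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.writeMatrixTSV <- function(M, path, idCol = "sample_id") {
  df <- data.frame(rownames(M), format(M, digits = 17, trim = TRUE,
                                       scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(idCol, colnames(M))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align samples across phenotype, covariate and genotype objects
#'
#' Takes the intersection of sample ids, preserving the phenotype order,
#' and subsets every object to it. The number of samples dropped from each
#' input is reported via message().
#'
#' @param Y a \linkS4class{PhenotypeMatrix}
#' @param X a \linkS4class{CovariateMatrix} or NULL
#' @param G a \linkS4class{GenotypeData} or NULL
#' @return list(Y = , X = , G = ) with identical sample ordering
#' @export
alignSamples <- function(Y, X = NULL, G = NULL) {
  ids <- sampleIDs(Y)
  if (!is.null(X)) ids <- ids[ids %in% sampleIDs(X)]
  if (!is.null(G)) ids <- ids[ids %in% sampleIDs(G)]
  if (length(ids) < 2L) stop("fewer than 2 samples shared across inputs")
  report <- function(what, before) {
    d <- before - length(ids)
    if (d > 0L) message("alignSamples: dropped ", d, " sample(s) from ", what)
  }
  report("phenotypes", length(sampleIDs(Y)))
  Y2 <- PhenotypeMatrix(as.matrix(Y)[ids, , drop = FALSE], featureCoords(Y))
  X2 <- NULL
  if (!is.null(X)) {
    report("covariates", length(sampleIDs(X)))
    X2 <- new("CovariateMatrix", values = as.matrix(X)[ids, , drop = FALSE],
              role = X@role)
  }
  G2 <- NULL
  if (!is.null(G)) {
    report("genotypes", length(sampleIDs(G)))
    G2 <- new("GenotypeData", dosages = dosages(G)[ids, , drop = FALSE],
              snpCoords = snpCoords(G), maf = mafs(G), cisMap = cisMap(G))
  }
  list(Y = Y2, X = X2, G = G2)
}
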