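# Accessors, coercions and show methods. Slot access outside this file is
# internal only; user code should go through these.

#' Construct a PhenotypeMatrix
#'
#' @param values numeric matrix, samples x features, with dimnames.
#' @param featureCoords optional data.frame (feature_id, chrom, start, end).
#' @return a \linkS4class{PhenotypeMatrix}
#' @export
PhenotypeMatrix <- function(values, featureCoords = NULL) {
  new("PhenotypeMatrix", values = as.matrix(values), featureCoords = featureCoords)
}

#' Construct a CovariateMatrix
#'
#' @param values numeric matrix, samples x covariates, with dimnames
#'   (zero columns allowed). Zero-variance columns are dropped with a
#'   warning: they carry no information and break downstream regressions.
#' @param role "known", "hidden_truth" or "inferred".
#' @return a \linkS4class{CovariateMatrix}
#' @export
CovariateMatrix <- function(values, role = c("known", "hidden_truth", "inferred")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("covariates must be numeric (encode categories first)")
  if (ncol(values) > 0L) {
    v <- apply(values, 2L, stats::var)
    if (any(v < 1e-24)) {
      warning("dropping zero-variance covariate(s): ",
              paste(colnames(values)[v < 1e-24], collapse = ", "))
      values <- values[, v >= 1e-24, drop = FALSE]
    }
  }
  new("CovariateMatrix", values = values, role = role)
}

#' Construct a GenotypeData object
#'
#' @param dosages numeric matrix samples x SNPs in [0, 2] with dimnames.
#' @param snpCoords data.frame (snp_id, chrom, pos).
#' @param maf optional folded minor-allele frequencies (computed from the
#'   dosages when missing).
#' @param cisMap named list feature_id -> integer SNP column indices.
#' @return a \linkS4class{GenotypeData}
#' @export
GenotypeData <- function(dosages, snpCoords = NULL, maf = NULL, cisMap = list()) {
  dosages <- as.matrix(dosages)
  if (is.null(snpCoords)) {
    snpCoords <- data.frame(snp_id = colnames(dosages), chrom = "chrUnknown",
                            pos = seq_len(ncol(dosages)), stringsAsFactors = FALSE)
  }
  if (is.null(maf)) {
    af <- colMeans(dosages) / 2
    maf <- pmin(af, 1 - af)
  }
  new("GenotypeData", dosages = dosages, snpCoords = snpCoords,
      maf = unname(maf), cisMap = cisMap)
}

#' @describeIn sampleIDs sample ids of a phenotype matrix
#' @export
setMethod("sampleIDs", "PhenotypeMatrix", function(x) rownames(x@values))
#' @describeIn sampleIDs sample ids of a covariate matrix
#' @export
setMethod("sampleIDs", "CovariateMatrix", function(x) rownames(x@values))
#' @describeIn sampleIDs sample ids of genotype dosages
#' @export
setMethod("sampleIDs", "GenotypeData", function(x) rownames(x@dosages))

#' @describeIn featureIDs feature ids of a phenotype matrix
#' @export
setMethod("featureIDs", "PhenotypeMatrix", function(x) colnames(x@values))

#' @rdname featureCoords
#' @param x a PhenotypeMatrix
#' @export
setMethod("featureCoords", "PhenotypeMatrix", function(x) x@featureCoords)

#' @export
setMethod("as.matrix", "PhenotypeMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "CovariateMatrix", function(x, ...) x@values)

#' @rdname dosages
#' @param x a GenotypeData
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)
#' @rdname snpCoords
#' @param x a GenotypeData
#' @export
setMethod("snpCoords", "GenotypeData", function(x) x@snpCoords)
#' @rdname mafs
#' @param x a GenotypeData
#' @export
setMethod("mafs", "GenotypeData", function(x) x@maf)
#' @rdname cisMap
#' @param x a GenotypeData
#' @export
setMethod("cisMap", "GenotypeData", function(x) x@cisMap)

#' @rdname pcScores
#' @param x a PCAResult
#' @export
setMethod("pcScores", "PCAResult", function(x) x@scores)
#' @rdname pcLoadings
#' @param x a PCAResult
#' @export
setMethod("pcLoadings", "PCAResult", function(x) x@loadings)
#' @rdname pve
#' @export
setMethod("pve", "PCAResult", function(x) x@pve)

#' @rdname selectedK
#' @export
setMethod("selectedK", "KSelection", function(x) x@K)
#' @rdname kDiagnostics
#' @export
setMethod("kDiagnostics", "KSelection", function(x) x@diagnostics)

#' @rdname hiddenComponents
#' @export
setMethod("hiddenComponents", "HCPFit", function(x) x@Z)
#' @rdname objectiveTrace
#' @export
setMethod("objectiveTrace", "HCPFit", function(x) x@objectiveTrace)

#' @rdname qtlTable
#' @export
setMethod("qtlTable", "QTLResultTable", function(x) x@table)

#' @rdname truePairs
#' @export
setMethod("truePairs", "SimulatedQTLData", function(x) x@truth)
#' @rdname realizedPVE
#' @export
setMethod("realizedPVE", "SimulatedQTLData", function(x) x@realizedPVE)

#' Known covariates of a simulated dataset
#' @param x a SimulatedQTLData
#' @return the known \linkS4class{CovariateMatrix}
#' @export
knownCovariates <- function(x) {
  stopifnot(is(x, "SimulatedQTLData"))
  x@X1
}

#' Hidden-truth covariates of a simulated dataset
#' @param x a SimulatedQTLData
#' @return the hidden-truth \linkS4class{CovariateMatrix}
#' @export
hiddenCovariates <- function(x) {
  stopifnot(is(x, "SimulatedQTLData"))
  x@X2
}

#' Phenotypes of a simulated dataset
#' @param x a SimulatedQTLData
#' @export
simPhenotypes <- function(x) {
  stopifnot(is(x, "SimulatedQTLData"))
  x@Y
}

#' Genotypes of a simulated dataset
#' @param x a SimulatedQTLData
#' @export
simGenotypes <- function(x) {
  stopifnot(is(x, "SimulatedQTLData"))
  x@G
}

setMethod("show", "PhenotypeMatrix", function(object) {
  cat("PhenotypeMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "features\n")
  if (!is.null(object@featureCoords)) cat("  feature coordinates attached\n")
})

setMethod("show", "CovariateMatrix", function(object) {
  cat("CovariateMatrix (", object@role, "): ", nrow(object@values),
      " samples x ", ncol(object@values), " covariates\n", sep = "")
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosages), "samples x",
      ncol(object@dosages), "SNPs;",
      length(object@cisMap), "features with cis maps\n")
})

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", ncol(object@scores), "components over",
      nrow(object@scores), "samples\n")
  cat("  top pve:", paste(sprintf("%.3f", utils::head(object@pve, 5L)),
                          collapse = " "), "\n")
})

setMethod("show", "KSelection", function(object) {
  cat("KSelection [", object@method, "]: K =", object@K, "\n")
})

setMethod("show", "HCPFit", function(object) {
  cat("HCPFit: K =", ncol(object@Z), "components,",
      object@iterations, "sweeps,",
      if (object@converged) "converged" else "not converged", "\n")
  cat("  final objective:", utils::tail(object@objectiveTrace, 1L), "\n")
})

setMethod("show", "QTLResultTable", function(object) {
  cat("QTLResultTable:", nrow(object@table), "pairs tested (n =",
      object@metadata$n, ", df =", object@metadata$df, ")\n")
})

setMethod("show", "SimulatedQTLData", function(object) {
  cat("SimulatedQTLData [", object@params$design, "]: ",
      nrow(object@Y@values), " samples, ", ncol(object@Y@values), " genes, ",
      ncol(object@G@dosages), " SNPs, ", nrow(object@truth),
      " causal pairs\n", sep = "")
})
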