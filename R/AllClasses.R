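#' @import methods
NULL

#' Molecular phenotype matrix
#'
#' Samples-by-features matrix of fully processed molecular phenotypes
#' (expression, splicing, polyadenylation, ... after upstream processing).
#' Sample and feature identifiers live in the dimnames; optional genomic
#' coordinates per feature (1-based) support cis-window lookups.
#'
#' @slot values numeric matrix, rows = samples, columns = features.
#' @slot featureCoords \code{NULL} or a data.frame with columns
#'   \code{feature_id}, \code{chrom}, \code{start}, \code{end} (1-based).
#' @export
setClass("PhenotypeMatrix",
         representation(values = "matrix", featureCoords = "ANY"),
         prototype(featureCoords = NULL))

setValidity("PhenotypeMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v))) return("values contain missing/non-finite entries")
  if (nrow(v) < 2L) return("need at least 2 samples")
  if (ncol(v) < 1L) return("need at least 1 feature")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("sample and feature ids (dimnames) are required")
  if (anyDuplicated(rownames(v))) return("duplicated sample ids")
  if (anyDuplicated(colnames(v))) return("duplicated feature ids")
  fc <- object@featureCoords
  if (!is.null(fc)) {
    need <- c("feature_id", "chrom", "start", "end")
    if (!is.data.frame(fc) || !all(need %in% names(fc)))
      return("featureCoords must have columns feature_id, chrom, start, end")
    if (!all(colnames(v) %in% fc$feature_id))
      return("featureCoords missing some features")
  }
  TRUE
})

#' Covariate matrix
#'
#' Samples-by-covariates matrix; \code{role} records whether the columns
#' are measured (known) covariates, the simulation ground truth, or
#' inferred covariates such as phenotype PCs.
#'
#' @slot values numeric matrix, rows = samples, columns = covariates.
#'   Zero columns are allowed (an empty covariate set).
#' @slot role one of \code{"known"}, \code{"hidden_truth"}, \code{"inferred"}.
#' @export
setClass("CovariateMatrix",
         representation(values = "matrix", role = "character"),
         prototype(role = "known"))

setValidity("CovariateMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (anyNA(v)) return("values contain missing entries")
  if (is.null(rownames(v))) return("sample ids (rownames) are required")
  if (ncol(v) > 0L && is.null(colnames(v))) return("covariate ids (colnames) are required")
  if (anyDuplicated(rownames(v))) return("duplicated sample ids")
  if (ncol(v) > 0L && anyDuplicated(colnames(v))) return("duplicated covariate ids")
  if (!object@role %in% c("known", "hidden_truth", "inferred"))
    return("role must be known, hidden_truth or inferred")
  TRUE
})

#' Genotype dosages with a cis-SNP map
#'
#' @slot dosages numeric matrix, rows = samples, columns = SNPs, entries in
#'   [0, 2] (alternate-allele counts, mean-imputed where missing).
#' @slot snpCoords data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based position).
#' @slot maf numeric vector of folded minor-allele frequencies per SNP.
#' @slot cisMap named list: feature_id -> integer indices of cis SNP columns.
#' @export
setClass("GenotypeData",
         representation(dosages = "matrix", snpCoords = "data.frame",
                        maf = "numeric", cisMap = "list"),
         prototype(cisMap = list()))

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  if (!is.numeric(d)) return("dosages must be numeric")
  if (anyNA(d)) return("dosages contain missing entries")
  if (any(d < -1e-9 | d > 2 + 1e-9)) return("dosages must lie in [0, 2]")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("sample ids and snp ids (dimnames) are required")
  if (nrow(object@snpCoords) != ncol(d)) return("snpCoords/dosages mismatch")
  if (length(object@maf) != ncol(d)) return("maf/dosages mismatch")
  if (length(object@cisMap)) {
    idx <- unlist(object@cisMap, use.names = FALSE)
    if (length(idx) && (min(idx) < 1L || max(idx) > ncol(d)))
      return("cisMap indexes outside the dosage matrix")
  }
  TRUE
})

#' Principal component analysis result
#'
#' @slot scores n x r matrix of component scores (samples x PCs).
#' @slot loadings p x r matrix of loadings (features x PCs).
#' @slot sdev r standard deviations (singular values / sqrt(n - 1)).
#' @slot pve r proportions of variance explained, non-increasing, summing
#'   to 1 over the full rank.
#' @slot center,scale logical flags recording the preprocessing applied.
#' @export
setClass("PCAResult",
         representation(scores = "matrix", loadings = "matrix",
                        sdev = "numeric", pve = "numeric",
                        center = "logical", scale = "logical"))

setValidity("PCAResult", function(object) {
  r <- ncol(object@scores)
  if (ncol(object@loadings) != r) return("scores/loadings rank mismatch")
  if (length(object@sdev) != r || length(object@pve) != r)
    return("sdev/pve length mismatch")
  if (any(object@pve < -1e-12 | object@pve > 1 + 1e-12)) return("pve outside [0, 1]")
  if (any(diff(object@pve) > 1e-10)) return("pve must be non-increasing")
  TRUE
})

#' Number-of-components selection
#'
#' @slot method \code{"elbow"} or \code{"be"}.
#' @slot K selected number of components (0 allowed: nothing stands out).
#' @slot diagnostics per-component statistics (distances for elbow;
#'   observed pve and permutation quantiles for BE).
#' @slot params the method parameters actually used.
#' @slot seed RNG seed for permutation-based selection (NULL for elbow).
#' @export
setClass("KSelection",
         representation(method = "character", K = "integer",
                        diagnostics = "data.frame", params = "list",
                        seed = "ANY"),
         prototype(seed = NULL))

setValidity("KSelection", function(object) {
  if (!object@method %in% c("elbow", "be")) return("method must be elbow or be")
  if (object@K < 0L || object@K > nrow(object@diagnostics))
    return("K outside [0, components examined]")
  TRUE
})

#' Hidden covariates with prior (HCP) fit
#'
#' @slot Z n x K hidden component matrix.
#' @slot B K x p coefficient matrix (components -> features).
#' @slot U K1 x K coefficients mapping known covariates to components.
#' @slot lambdas penalty weights (lambda1, lambda2, lambda3).
#' @slot objectiveTrace objective value after each coordinate-descent sweep.
#' @slot iterations number of sweeps performed.
#' @slot converged whether the relative-change tolerance was reached.
#' @export
setClass("HCPFit",
         representation(Z = "matrix", B = "matrix", U = "matrix",
                        lambdas = "numeric", objectiveTrace = "numeric",
                        iterations = "integer", converged = "logical"))

setValidity("HCPFit", function(object) {
  K <- ncol(object@Z)
  if (nrow(object@B) != K) return("Z/B dimension mismatch")
  if (ncol(object@U) != K) return("Z/U dimension mismatch")
  if (length(object@lambdas) != 3L || any(object@lambdas < 0))
    return("lambdas must be 3 non-negative reals")
  tr <- object@objectiveTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-9 * pmax(1, abs(tr[-length(tr)]))))
    return("objectiveTrace must be non-increasing")
  TRUE
})

#' QTL association results
#'
#' One row per (feature, SNP) pair tested: effect estimate per alternate
#' allele, standard error, t statistic, two-sided p-value at
#' df = n - (#covariates + 2), and Benjamini-Hochberg q-value over the
#' emitted rows.
#'
#' @slot table data.frame with columns feature_id, snp_id, beta, se,
#'   t_stat, p_value, q_value.
#' @slot metadata list: covariate ids used, n, df, scope, notes on skipped
#'   pairs.
#' @export
setClass("QTLResultTable",
         representation(table = "data.frame", metadata = "list"),
         prototype(metadata = list()))

setValidity("QTLResultTable", function(object) {
  need <- c("feature_id", "snp_id", "beta", "se", "t_stat", "p_value", "q_value")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  p <- object@table$p_value
  if (any(!is.na(p) & (p <= 0 | p > 1))) return("p_value outside (0, 1]")
  TRUE
})

#' Simulated QTL dataset with ground truth
#'
#' @slot Y simulated \linkS4class{PhenotypeMatrix}.
#' @slot G simulated \linkS4class{GenotypeData} with per-gene cis blocks.
#' @slot X1 known \linkS4class{CovariateMatrix} (possibly 0 columns).
#' @slot X2 hidden-truth \linkS4class{CovariateMatrix}.
#' @slot truth data.frame of causal pairs: feature_id, snp_id, effect,
#'   type ("cis" or "trans").
#' @slot realizedPVE per-gene realized variance shares of the genotype,
#'   covariate (and trans) components.
#' @slot params the simulation parameters used.
#' @export
setClass("SimulatedQTLData",
         representation(Y = "PhenotypeMatrix", G = "GenotypeData",
                        X1 = "CovariateMatrix", X2 = "CovariateMatrix",
                        truth = "data.frame", realizedPVE = "data.frame",
                        params = "list"))

setValidity("SimulatedQTLData", function(object) {
  if (!all(c("feature_id", "snp_id", "effect", "type") %in% names(object@truth)))
    return("truth must have columns feature_id, snp_id, effect, type")
  if (!all(object@truth$snp_id %in% colnames(object@G@dosages)))
    return("truth references unknown SNPs")
  TRUE
})
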