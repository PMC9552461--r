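# Factor-redundancy diagnostics: correlation clustering of inferred
# factors (how many are distinct?) and factor-to-PC matching summaries of
# the absolute correlation matrix.

#' Factor correlation-cluster report
#'
#' @slot threshold absolute-correlation threshold used for the cut.
#' @slot numFactors number of factors clustered.
#' @slot numClusters number of clusters found.
#' @slot assignment integer cluster label per factor.
#' @export
setClass("ClusterReport",
         representation(threshold = "numeric", numFactors = "integer",
                        numClusters = "integer", assignment = "integer"))

setValidity("ClusterReport", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must be in (0, 1)")
  if (object@numClusters < 1L || object@numClusters > object@numFactors)
    return("numClusters outside [1, numFactors]")
  TRUE
})

#' Factor-to-PC match report
#'
#' @slot permutation integer: factor i is matched to PC permutation[i].
#' @slot pairCor absolute correlation of each matched pair.
#' @slot diagMean,offdiagMean means of the diagonal and off-diagonal
#'   entries of the reordered absolute correlation matrix.
#' @slot diagSE,offdiagSE standard errors of those means.
#' @slot corMatrix the reordered absolute correlation matrix
#'   (factors x PCs).
#' @slot method "greedy" or "optimal".
#' @export
setClass("MatchReport",
         representation(permutation = "integer", pairCor = "numeric",
                        diagMean = "numeric", offdiagMean = "numeric",
                        diagSE = "numeric", offdiagSE = "numeric",
                        corMatrix = "matrix", method = "character"))

setValidity("MatchReport", function(object) {
  K <- length(object@permutation)
  if (!setequal(object@permutation, seq_len(K)))
    return("permutation must be a bijection onto the matched PCs")
  if (abs(object@diagMean - mean(object@pairCor)) > 1e-8)
    return("diagMean must equal the mean of pairCor")
  TRUE
})

setMethod("show", "ClusterReport", function(object) {
  cat("ClusterReport: ", object@numFactors, " factors -> ",
      object@numClusters, " cluster(s) at |cor| > ", object@threshold,
      "\n", sep = "")
})

setMethod("show", "MatchReport", function(object) {
  cat("MatchReport (", object@method, "): diag mean ",
      sprintf("%.3f", object@diagMean), " (se ",
      sprintf("%.3g", object@diagSE), "), offdiag mean ",
      sprintf("%.3f", object@offdiagMean), " (se ",
      sprintf("%.3g", object@offdiagSE), ")\n", sep = "")
})

#' Count distinct factors by correlation clustering
#'
#' Hierarchically clusters factors with complete linkage on the distance
#' 1 - |cor| and cuts the tree so that within every cluster all pairwise
#' absolute correlations exceed `threshold` strictly (a pair at exactly
#' the threshold lands in different clusters). The number of clusters can
#' be read as the number of distinct, non-repetitive factors.
#'
#' @param factors a \linkS4class{CovariateMatrix} (or samples x factors
#'   matrix); every column must have nonzero variance
#' @param threshold absolute-correlation threshold in (0, 1); 0.99, 0.9
#'   and 0.8 are conventional choices
#' @return a \linkS4class{ClusterReport}
#' @export
countFactorClusters <- function(factors, threshold = 0.9) {
  v <- if (is(factors, "CovariateMatrix")) as.matrix(factors) else as.matrix(factors)
  if (nrow(v) < 2L || ncol(v) < 1L) stop("need >= 2 samples and >= 1 factor")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds < .Machine$double.eps))
    stop("zero-variance factor(s): correlation undefined")
  K <- ncol(v)
  if (K == 1L) {
    return(new("ClusterReport", threshold = threshold, numFactors = 1L,
               numClusters = 1L, assignment = 1L))
  }
  ac <- abs(stats::cor(v))
  d <- stats::as.dist(1 - ac)
  hc <- stats::hclust(d, method = "complete")
  # strict cut: merges at exactly height 1 - threshold stay separate
  assign <- stats::cutree(hc, h = (1 - threshold) - 1e-9)
  new("ClusterReport", threshold = threshold, numFactors = K,
      numClusters = as.integer(max(assign)), assignment = as.integer(assign))
}

# exhaustive best-bijection assignment maximizing the sum of |cor|
.optimalAssignment <- function(ac) {
  K <- nrow(ac)
  if (K > 9L) stop("optimal matching supported for up to 9 factors")
  perms <- .allPerms(K)
  best <- NULL; bestVal <- -Inf
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    val <- sum(ac[cbind(seq_len(K), pm)])
    if (val > bestVal) { bestVal <- val; best <- pm }
  }
  best
}

.allPerms <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPerms(K - 1L)
  out <- matrix(0L, nrow = nrow(sub) * K, ncol = K)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(K)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ] + (sub[i, ] >= pos), pos, after = pos - 1L)
  }
  out
}

#' Match inferred factors to principal components
#'
#' Pairs factors with PCs on the absolute Pearson correlation matrix.
#' Greedy matching (default) repeatedly takes the largest remaining
#' |cor| and removes its row and column; "optimal" searches all bijections
#' (exhaustive, up to 9 factors). The reordered matrix is summarized by
#' the mean of its diagonal (matched-pair correlations) and the mean of
#' its off-diagonal entries, each with a standard error. Factors that
#' genuinely are the PCs give diagonal mean 1 and off-diagonal mean 0.
#'
#' @param factors a \linkS4class{CovariateMatrix} of K inferred factors
#' @param pcs a \linkS4class{CovariateMatrix} (or score matrix) with at
#'   least K PCs; the top K are used
#' @param method "greedy" or "optimal"
#' @return a \linkS4class{MatchReport}
#' @export
matchFactorsToPCs <- function(factors, pcs, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  fv <- if (is(factors, "CovariateMatrix")) as.matrix(factors) else as.matrix(factors)
  pv <- if (is(pcs, "CovariateMatrix")) as.matrix(pcs) else as.matrix(pcs)
  if (nrow(fv) != nrow(pv)) stop("factors and PCs must share samples")
  K <- ncol(fv)
  if (ncol(pv) < K) stop("fewer PCs than factors")
  pv <- pv[, seq_len(K), drop = FALSE]
  ac <- abs(stats::cor(fv, pv))
  if (anyNA(ac)) stop("zero-variance column(s): correlation undefined")
  if (method == "greedy") {
    perm <- integer(K)
    work <- ac
    for (step in seq_len(K)) {
      ij <- arrayInd(which.max(work), dim(work))
      perm[ij[1L]] <- ij[2L]
      work[ij[1L], ] <- -Inf
      work[, ij[2L]] <- -Inf
    }
  } else {
    perm <- .optimalAssignment(ac)
  }
  # reorder PCs so the matched PC of factor i sits in column i
  reordered <- ac[, perm, drop = FALSE]
  pair <- diag(reordered)
  off <- reordered[row(reordered) != col(reordered)]
  new("MatchReport", permutation = as.integer(perm), pairCor = pair,
      diagMean = mean(pair),
      offdiagMean = if (length(off)) mean(off) else 0,
      diagSE = if (length(pair) > 1L) stats::sd(pair) / sqrt(length(pair)) else 0,
      offdiagSE = if (length(off) > 1L) stats::sd(off) / sqrt(length(off)) else 0,
      corMatrix = reordered, method = method)
}
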