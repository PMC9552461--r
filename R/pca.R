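# PCA of the phenotype matrix and PCA-based covariate inference, including
# residualization on known covariates and the known-covariate filtering
# rule used by the direct variant.

#' Principal component analysis of a phenotype matrix
#'
#' Thin wrapper around the singular value decomposition (via
#' \code{stats::prcomp}) with a deterministic sign convention: each
#' component is flipped so that its largest-magnitude loading is positive,
#' making scores reproducible across linear-algebra backends. Centering is
#' applied before scaling; scaling uses the n-1 standard deviation.
#' pve_k = sdev_k^2 / sum(sdev^2) over all r = min(n-1, p) components.
#'
#' @param Y a \linkS4class{PhenotypeMatrix} (or plain matrix, samples x
#'   features)
#' @param center,scale preprocessing flags (both TRUE by default; scaling
#'   requires nonzero-variance features)
#' @return a \linkS4class{PCAResult}
#' @export
runPCA <- function(Y, center = TRUE, scale = TRUE) {
  v <- if (is(Y, "PhenotypeMatrix")) as.matrix(Y) else as.matrix(Y)
  if (nrow(v) < 2L) stop("need at least 2 samples")
  if (scale) {
    s <- apply(v, 2L, stats::sd)
    if (any(s < .Machine$double.eps^0.5))
      stop("zero-variance feature(s) cannot be scaled")
  }
  pc <- stats::prcomp(v, center = center, scale. = scale)
  r <- min(nrow(v) - 1L, ncol(v))
  scores <- pc$x[, seq_len(r), drop = FALSE]
  loadings <- pc$rotation[, seq_len(r), drop = FALSE]
  sdev <- pc$sdev[seq_len(r)]
  # sign convention: largest |loading| positive
  for (k in seq_len(r)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  tot <- sum(pc$sdev^2)
  pvek <- sdev^2 / tot
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(r))
  rownames(scores) <- rownames(v)
  new("PCAResult", scores = scores, loadings = loadings, sdev = sdev,
      pve = pvek, center = center, scale = scale)
}

#' Regress known covariates out of a phenotype matrix
#'
#' Replaces each feature by its OLS residual on an intercept plus the
#' known covariates. Collinear covariate columns are dropped with a
#' warning. With an empty covariate set this mean-centers each feature.
#'
#' @param Y a \linkS4class{PhenotypeMatrix}
#' @param X1 a \linkS4class{CovariateMatrix} (known), possibly 0 columns,
#'   or NULL
#' @return a residual \linkS4class{PhenotypeMatrix}
#' @export
regressOut <- function(Y, X1 = NULL) {
  stopifnot(is(Y, "PhenotypeMatrix"))
  v <- as.matrix(Y)
  Xv <- if (is.null(X1)) NULL else as.matrix(X1)
  if (!is.null(Xv) && ncol(Xv) > 0L) {
    d <- .designQR(Xv, nrow(v))
    if (length(d$keep) < ncol(Xv))
      warning("dropped ", ncol(Xv) - length(d$keep),
              " collinear known covariate column(s)")
    res <- qr.resid(d$qr, v)
  } else {
    res <- sweep(v, 2L, colMeans(v), "-")
  }
  dimnames(res) <- dimnames(v)
  PhenotypeMatrix(res, featureCoords = featureCoords(Y))
}

#' Filter known covariates captured by inferred covariates
#'
#' For each known covariate, fits OLS of the covariate on an intercept
#' plus all inferred covariates and drops it when the unadjusted R^2 is at
#' least `r2Threshold`. Known covariates the PCs already capture are
#' redundant in the QTL regression; the rest are retained.
#'
#' @param X1 known \linkS4class{CovariateMatrix}
#' @param XInferred inferred \linkS4class{CovariateMatrix} (e.g. top PCs)
#' @param r2Threshold drop threshold on unadjusted R^2 (default 0.9)
#' @return list(kept = CovariateMatrix, dropped = character ids,
#'   r2 = named numeric per-covariate R^2)
#' @export
filterKnownCovariates <- function(X1, XInferred, r2Threshold = 0.9) {
  stopifnot(is(X1, "CovariateMatrix"), is(XInferred, "CovariateMatrix"))
  .checkSampleAlignment(X1, XInferred, "known and inferred covariates")
  v1 <- as.matrix(X1)
  vi <- as.matrix(XInferred)
  if (ncol(v1) == 0L)
    return(list(kept = X1, dropped = character(0), r2 = numeric(0)))
  r2 <- vapply(seq_len(ncol(v1)), function(j) .olsR2(v1[, j], vi), numeric(1L))
  names(r2) <- colnames(v1)
  drop <- r2 >= r2Threshold
  kept <- new("CovariateMatrix", values = v1[, !drop, drop = FALSE],
              role = X1@role)
  list(kept = kept, dropped = colnames(v1)[drop], r2 = r2)
}

#' Infer hidden covariates by PCA
#'
#' Two variants. `pca_direct`: run PCA on the (transformed) phenotype
#' matrix directly and afterwards drop the known covariates that the top K
#' PCs capture well (unadjusted R^2 >= `r2Threshold`). `pca_resid`: first
#' regress the known covariates out of the phenotypes, re-center/scale the
#' residuals, then run PCA; the known covariates are kept unfiltered.
#' The direct variant is the recommended default: it is simpler and the
#' known covariates cannot distort the PCs.
#'
#' @param Y a \linkS4class{PhenotypeMatrix}, already transformed as
#'   desired (see [transformPhenotypes()])
#' @param X1 known \linkS4class{CovariateMatrix} or NULL
#' @param variant "pca_direct" or "pca_resid"
#' @param K number of PCs to return as inferred covariates
#'   (1 <= K <= min(n-1, p))
#' @param center,scale flags passed to [runPCA()]
#' @param r2Threshold known-covariate filter threshold (pca_direct only)
#' @return list(inferred = CovariateMatrix of K PCs, knownUsed =
#'   CovariateMatrix, pca = PCAResult, filter = filter report or NULL)
#' @export
inferCovariates <- function(Y, X1 = NULL, variant = c("pca_direct", "pca_resid"),
                            K, center = TRUE, scale = TRUE, r2Threshold = 0.9) {
  stopifnot(is(Y, "PhenotypeMatrix"))
  variant <- match.arg(variant)
  n <- nrow(as.matrix(Y))
  p <- ncol(as.matrix(Y))
  if (K < 1L || K > min(n - 1L, p))
    stop("K must be in [1, min(n-1, p)] = [1, ", min(n - 1L, p), "]")
  if (is.null(X1))
    X1 <- new("CovariateMatrix",
              values = matrix(numeric(0), nrow = n, ncol = 0L,
                              dimnames = list(sampleIDs(Y), NULL)),
              role = "known")
  filter <- NULL
  if (variant == "pca_direct") {
    pca <- runPCA(Y, center = center, scale = scale)
    XInf <- new("CovariateMatrix",
                values = pcScores(pca)[, seq_len(K), drop = FALSE],
                role = "inferred")
    if (ncol(as.matrix(X1)) > 0L) {
      filter <- filterKnownCovariates(X1, XInf, r2Threshold = r2Threshold)
      X1used <- filter$kept
    } else X1used <- X1
  } else {
    Yres <- regressOut(Y, X1)
    pca <- runPCA(Yres, center = center, scale = scale)
    XInf <- new("CovariateMatrix",
                values = pcScores(pca)[, seq_len(K), drop = FALSE],
                role = "inferred")
    X1used <- X1
  }
  list(inferred = XInf, knownUsed = X1used, pca = pca, filter = filter)
}
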