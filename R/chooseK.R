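# Selection of the number of PCs: automatic elbow detection on the scree,
# and the Buja-Eyuboglu (BE) permutation test.

#' Automatic elbow detection on a scree
#'
#' Draws the chord from the first scree point (1, pve_1) to the last
#' (r, pve_r) and computes each point's perpendicular distance to it. The
#' farthest point is the elbow: the first component that sits on the flat
#' part of the scree. K is the number of components retained before it,
#' i.e. the elbow's index minus one. Exact distance ties resolve to the
#' smallest index. A perfectly linear scree has no elbow and yields K = 0.
#'
#' @param pveVec non-increasing vector of per-component proportions of
#'   variance explained (length >= 3)
#' @return a \linkS4class{KSelection} with per-component distances in the
#'   diagnostics
#' @export
selectKElbow <- function(pveVec) {
  pveVec <- as.numeric(pveVec)
  r <- length(pveVec)
  if (r < 3L) stop("need at least 3 components for elbow detection")
  if (any(pveVec < 0)) stop("pve must be non-negative")
  if (any(diff(pveVec) > 1e-12)) stop("pve must be non-increasing (not a scree)")
  x <- seq_len(r)
  # perpendicular distance from (x_k, pve_k) to the chord (x_1,pve_1)-(x_r,pve_r)
  dx <- r - 1
  dy <- pveVec[r] - pveVec[1L]
  len <- sqrt(dx^2 + dy^2)
  dist <- abs(dy * (x - 1) - dx * (pveVec - pveVec[1L])) / len
  elbow <- which.max(dist) # ties: which.max takes the smallest index
  K <- elbow - 1L
  diag <- data.frame(component = x, pve = pveVec, distance = dist)
  new("KSelection", method = "elbow", K = as.integer(K), diagnostics = diag,
      params = list(), seed = NULL)
}

#' Buja-Eyuboglu permutation selection of K
#'
#' Parallel-analysis choice of the number of PCs: a component is retained
#' when it explains more variance than expected by chance. For each of B
#' permutations, every feature column of the (centered/scaled) matrix is
#' permuted independently — destroying inter-feature correlation while
#' preserving marginals — and the permuted pve spectrum is recorded. A
#' component is significant when its observed pve exceeds the empirical
#' (1 - alpha) quantile of its B permuted values. Selection stops at the
#' first non-significant component, so the retained PCs always form a
#' prefix.
#'
#' @param Y a \linkS4class{PhenotypeMatrix} (n >= 3)
#' @param B number of permutations (default 20)
#' @param alpha significance level (default 0.05)
#' @param seed RNG seed (required for reproducibility)
#' @param center,scale preprocessing flags passed to [runPCA()]
#' @param maxComponents cap on the number of components examined (default
#'   all min(n-1, p))
#' @return a \linkS4class{KSelection}; diagnostics hold the observed pve
#'   and the permutation quantile per component
#' @export
selectKBE <- function(Y, B = 20L, alpha = 0.05, seed = 1L, center = TRUE,
                      scale = TRUE, maxComponents = NULL) {
  stopifnot(is(Y, "PhenotypeMatrix"))
  v <- as.matrix(Y)
  if (nrow(v) < 3L) stop("need at least 3 samples")
  if (B < 1L) stop("B must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  v <- .centerScale(v, center = center, scale = scale)
  obs <- runPCA(v, center = FALSE, scale = FALSE)
  r <- length(pve(obs))
  if (!is.null(maxComponents)) r <- min(r, maxComponents)
  obsPve <- pve(obs)[seq_len(r)]
  n <- nrow(v)
  permPve <- matrix(NA_real_, nrow = B, ncol = r)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- matrix(0L, nrow = n, ncol = ncol(v))
    for (j in seq_len(ncol(v))) idx[, j] <- sample.int(n)
    vp <- matrix(v[cbind(as.vector(idx), rep(seq_len(ncol(v)), each = n))],
                 nrow = n)
    sv <- svd(vp, nu = 0L, nv = 0L)$d
    pv <- sv^2 / sum(sv^2)
    permPve[b, ] <- pv[seq_len(r)]
  }
  # type-1 empirical quantile of the B permuted values per component
  qidx <- max(1L, ceiling((1 - alpha) * B))
  quant <- apply(permPve, 2L, function(x) sort(x)[qidx])
  signif <- obsPve > quant
  K <- if (signif[1L]) which.min(c(signif, FALSE)) - 1L else 0L
  diag <- data.frame(component = seq_len(r), pve = obsPve,
                     perm_quantile = quant, significant = signif)
  new("KSelection", method = "be", K = as.integer(K), diagnostics = diag,
      params = list(B = B, alpha = alpha, center = center, scale = scale),
      seed = seed)
}
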