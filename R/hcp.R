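# Hidden covariates with prior (HCP): penalized matrix reconstruction with
# the hidden components coupled to the known covariates, fit by cyclic
# closed-form coordinate descent.

#' Fit hidden covariates with prior (HCP)
#'
#' Minimizes
#' \deqn{||Y - Z B||_F^2 + \lambda_1 ||Z - X_1 U||_F^2 +
#'       \lambda_2 ||B||_F^2 + \lambda_3 ||U||_F^2}
#' over Z (n x K hidden components), B (K x p) and U (K1 x K) by cyclic
#' block updates, each of which is the exact closed-form minimizer given
#' the other two blocks, so the objective never increases. Initialization
#' is deterministic: Z starts at the top-K PC scores of Y and B, U at
#' their closed-form updates given Z. Y is expected centered/scaled
#' upstream.
#'
#' Update order per sweep is Z, then B, then U; iteration stops when the
#' relative objective change falls below `tol` or after `maxIter` sweeps.
#'
#' @param Y a \linkS4class{PhenotypeMatrix}, centered/scaled upstream
#' @param X1 known \linkS4class{CovariateMatrix} (must be non-empty: the
#'   prior couples Z to it)
#' @param K number of hidden components (>= 1)
#' @param lambdas numeric length 3, (lambda1, lambda2, lambda3), all >= 0
#' @param tol relative objective-change tolerance (default 1e-6)
#' @param maxIter maximum sweeps (default 100)
#' @return an \linkS4class{HCPFit}
#' @export
fitHCP <- function(Y, X1, K, lambdas = c(1, 1, 1), tol = 1e-6, maxIter = 100L) {
  stopifnot(is(Y, "PhenotypeMatrix"), is(X1, "CovariateMatrix"))
  .checkSampleAlignment(Y, X1, "phenotypes and known covariates")
  Yv <- as.matrix(Y)
  Xv <- as.matrix(X1)
  if (ncol(Xv) == 0L) stop("HCP requires a non-empty known covariate matrix")
  if (K < 1L) stop("K must be >= 1")
  if (length(lambdas) != 3L || any(lambdas < 0)) stop("lambdas must be 3 non-negative reals")
  l1 <- lambdas[1L]; l2 <- lambdas[2L]; l3 <- lambdas[3L]
  n <- nrow(Yv); p <- ncol(Yv); K1 <- ncol(Xv)
  if (l1 == 0 && K > qr(Yv)$rank)
    warning("lambda1 = 0 with K > rank(Y): component scale is unidentifiable")

  obj <- function(Z, B, U) {
    sum((Yv - Z %*% B)^2) + l1 * sum((Z - Xv %*% U)^2) +
      l2 * sum(B^2) + l3 * sum(U^2)
  }
  updateB <- function(Z) solve(crossprod(Z) + l2 * diag(K), crossprod(Z, Yv))
  updateU <- function(Z) {
    if (l1 == 0) return(matrix(0, K1, K))
    solve(crossprod(Xv) + (l3 / l1) * diag(K1), crossprod(Xv, Z))
  }
  updateZ <- function(B, U) {
    t(solve(tcrossprod(B) + l1 * diag(K), t(Yv %*% t(B) + l1 * Xv %*% U)))
  }

  # deterministic initialization: top-K PC scores, then closed-form B, U
  Z <- runPCA(Yv, center = FALSE, scale = FALSE)@scores[, seq_len(K), drop = FALSE]
  B <- updateB(Z)
  U <- updateU(Z)
  trace <- obj(Z, B, U)
  if (!is.finite(trace)) stop("non-finite HCP objective at initialization")
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Z <- updateZ(B, U)
    B <- updateB(Z)
    U <- updateU(Z)
    o <- obj(Z, B, U)
    if (!is.finite(o)) stop("non-finite HCP objective at sweep ", it)
    trace <- c(trace, o)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - o) <= tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  rownames(Z) <- rownames(Yv)
  colnames(Z) <- paste0("HCP", seq_len(K))
  new("HCPFit", Z = Z, B = B, U = U, lambdas = as.numeric(lambdas),
      objectiveTrace = trace, iterations = it, converged = converged)
}
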