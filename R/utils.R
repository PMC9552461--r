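# Internal helpers shared across modules: seeded stream splitting and
# small OLS primitives built on the QR decomposition.

#' Derive a child seed from a master seed and a stage label
#'
#' Labeled stream splitting: every stochastic stage of a workflow draws
#' its own seed from the master seed and a human-readable label, so
#' stages are reproducible independently of each other. The label is
#' hashed with a polynomial rolling hash; the result stays below 2^31 and
#' is a valid \code{set.seed()} argument on 32-bit integer platforms.
#'
#' @param seed master seed (integer-like scalar)
#' @param label character stage label
#' @return an integer seed
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((h + (seed %% m) * 69069) %% m)
}

# QR of [1, X] with pivoting; drops collinear columns (keeps the first of
# any dependent set). Returns the qr object plus the indices of X columns
# retained.
.designQR <- function(X, n) {
  if (is.null(X) || NCOL(X) == 0L) {
    D <- matrix(1, nrow = n, ncol = 1L)
    qrD <- qr(D)
    return(list(qr = qrD, keep = integer(0)))
  }
  X <- as.matrix(X)
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keepD <- sort(qrD$pivot[seq_len(qrD$rank)])
    D <- D[, keepD, drop = FALSE]
    qrD <- qr(D)
    keep <- keepD[keepD > 1L] - 1L
  } else {
    keep <- seq_len(ncol(X))
  }
  list(qr = qrD, keep = keep)
}

# Residuals of each column of Y on [1, X]; X may be NULL (centering only).
.olsResiduals <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  d <- .designQR(X, nrow(Y))
  res <- qr.resid(d$qr, Y)
  attr(res, "keep") <- d$keep
  res
}

# Unadjusted R^2 of response y on [1, X].
.olsR2 <- function(y, X) {
  y <- as.numeric(y)
  res <- .olsResiduals(matrix(y, ncol = 1L), X)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("response has zero variance; R^2 undefined")
  1 - sum(res^2) / tss
}

# Adjusted R^2 with the standard small-sample correction
# 1 - (1 - R^2) (N - 1) / (N - k - 1), k = number of predictors.
.olsAdjR2 <- function(y, X) {
  n <- length(y)
  k <- NCOL(X)
  if (k >= n - 1L) stop("adjusted R^2 undefined: predictors >= samples - 1")
  r2 <- .olsR2(y, X)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

# Column-wise center and/or scale with the n-1 sd denominator.
.centerScale <- function(M, center = TRUE, scale = TRUE) {
  M <- as.matrix(M)
  if (center) M <- sweep(M, 2L, colMeans(M), "-")
  if (scale) {
    s <- sqrt(colSums(M^2) / (nrow(M) - 1L))
    if (any(s < .Machine$double.eps^0.5)) {
      bad <- colnames(M)[s < .Machine$double.eps^0.5]
      if (is.null(bad)) bad <- which(s < .Machine$double.eps^0.5)
      stop("zero-variance feature(s) cannot be scaled: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    M <- sweep(M, 2L, s, "/")
  }
  M
}

# Fast column-wise sample variance (n-1 denominator).
.colVars <- function(M) {
  n <- nrow(M)
  (colSums(M^2) - n * colMeans(M)^2) / (n - 1L)
}

.checkSampleAlignment <- function(a, b, what = "inputs") {
  ia <- sampleIDs(a)
  ib <- sampleIDs(b)
  if (length(ia) != length(ib) || !all(ia == ib)) {
    offenders <- union(setdiff(ia, ib), setdiff(ib, ia))
    stop("sample mismatch between ", what, ": ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  }
  invisible(TRUE)
}
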