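# Nominal-pass QTL association engine: per (feature, SNP) linear
# regression of phenotype on dosage plus covariates, implemented by
# Frisch-Waugh-Lovell residualization (the Matrix-eQTL strategy):
# covariates are projected out of phenotypes and dosages once, then each
# pair reduces to a simple regression on residuals with
# df = n - (#covariates + 2). This is algebraically identical to the full
# per-pair OLS fit.

#' Map QTL associations by linear regression
#'
#' For every feature j and SNP l in scope, fits
#' \code{Y[, j] ~ dosage_l + X} (with intercept) and records the dosage
#' coefficient's estimate, standard error, t statistic and two-sided
#' p-value at df = n - (#covariates + 2). q-values are Benjamini-Hochberg
#' adjusted over all emitted finite p-values (global by default,
#' per-feature optionally). Pairs whose in-sample dosage variance is below
#' 1e-12 after residualization input checks (monomorphic in sample) are
#' emitted with NA statistics and excluded from the adjustment. Collinear
#' covariate columns are pruned before fitting.
#'
#' @param Y a \linkS4class{PhenotypeMatrix}
#' @param G a \linkS4class{GenotypeData}
#' @param X a \linkS4class{CovariateMatrix} or NULL (no covariates)
#' @param scope "cis" (pairs from the cis map) or "all_pairs"
#' @param bhScope "global" (default) or "per_feature" BH adjustment
#' @return a \linkS4class{QTLResultTable}
#' @export
mapQTL <- function(Y, G, X = NULL, scope = c("cis", "all_pairs"),
                   bhScope = c("global", "per_feature")) {
  stopifnot(is(Y, "PhenotypeMatrix"), is(G, "GenotypeData"))
  scope <- match.arg(scope)
  bhScope <- match.arg(bhScope)
  .checkSampleAlignment(Y, G, "phenotypes and genotypes")
  if (!is.null(X)) .checkSampleAlignment(Y, X, "phenotypes and covariates")
  Yv <- as.matrix(Y)
  Dv <- dosages(G)
  Xv <- if (is.null(X)) NULL else as.matrix(X)
  n <- nrow(Yv)
  if (scope == "cis" && length(cisMap(G)) == 0L)
    stop("scope = 'cis' requires a cis map on the genotype data")

  d <- .designQR(Xv, n)
  ncov <- length(d$keep)
  if (!is.null(Xv) && ncov < ncol(Xv))
    message("mapQTL: pruned ", ncol(Xv) - ncov, " collinear covariate column(s)")
  df <- n - (ncov + 2L)
  if (df < 1L) stop("non-positive residual degrees of freedom")
  Ry <- qr.resid(d$qr, Yv)
  Rg <- qr.resid(d$qr, Dv)
  gss <- colSums(Rg^2)
  yss <- colSums(Ry^2)
  mono <- .colVars(Dv) < 1e-12

  feats <- featureIDs(Y)
  snpIds <- colnames(Dv)
  pairFeature <- character(0); pairSnp <- integer(0)
  if (scope == "cis") {
    cm <- cisMap(G)
    feats <- intersect(feats, names(cm))
    lens <- vapply(feats, function(f) length(cm[[f]]), integer(1L))
    pairFeature <- rep(feats, lens)
    pairSnp <- unlist(cm[feats], use.names = FALSE)
  } else {
    pairFeature <- rep(feats, each = ncol(Dv))
    pairSnp <- rep(seq_len(ncol(Dv)), times = length(feats))
  }
  m <- length(pairFeature)
  beta <- se <- tstat <- pval <- rep(NA_real_, m)

  featIdx <- match(pairFeature, featureIDs(Y))
  # vectorized per feature: all its SNPs at once
  for (f in unique(featIdx)) {
    rows <- which(featIdx == f)
    s <- pairSnp[rows]
    ok <- !mono[s] & gss[s] > 1e-12
    if (!any(ok)) next
    sok <- s[ok]
    xty <- as.numeric(crossprod(Rg[, sok, drop = FALSE], Ry[, f]))
    b <- xty / gss[sok]
    rss <- pmax(yss[f] - b * xty, 0)
    s2 <- rss / df
    seb <- sqrt(s2 / gss[sok])
    tt <- b / seb
    pv <- 2 * stats::pt(-abs(tt), df)
    idx <- rows[ok]
    beta[idx] <- b; se[idx] <- seb; tstat[idx] <- tt
    pval[idx] <- pmax(pv, .Machine$double.xmin) # keep p in (0, 1]
  }
  nSkipped <- sum(is.na(pval))
  if (nSkipped > 0L)
    message("mapQTL: ", nSkipped,
            " pair(s) skipped (monomorphic or zero-variance dosage in sample)")

  tab <- data.frame(feature_id = pairFeature, snp_id = snpIds[pairSnp],
                    beta = beta, se = se, t_stat = tstat, p_value = pval,
                    q_value = NA_real_, stringsAsFactors = FALSE)
  fin <- !is.na(tab$p_value)
  if (bhScope == "global") {
    tab$q_value[fin] <- stats::p.adjust(tab$p_value[fin], method = "BH")
  } else {
    for (f in unique(tab$feature_id)) {
      i <- fin & tab$feature_id == f
      tab$q_value[i] <- stats::p.adjust(tab$p_value[i], method = "BH")
    }
  }
  covIds <- if (is.null(Xv)) character(0) else colnames(Xv)[d$keep]
  new("QTLResultTable", table = tab,
      metadata = list(covariates = covIds, n = n, df = df, scope = scope,
                      bh_scope = bhScope, skipped = nSkipped))
}

#' Subset a QTL table to significant rows
#'
#' Rows with Benjamini-Hochberg q-value at or below `fdr`.
#'
#' @param res a \linkS4class{QTLResultTable}
#' @param fdr false discovery rate threshold (default 0.05)
#' @return a \linkS4class{QTLResultTable} containing only the significant
#'   rows (possibly zero rows)
#' @export
callSignificant <- function(res, fdr = 0.05) {
  stopifnot(is(res, "QTLResultTable"))
  tab <- qtlTable(res)
  keep <- !is.na(tab$q_value) & tab$q_value <= fdr
  new("QTLResultTable", table = tab[keep, , drop = FALSE],
      metadata = c(res@metadata, list(fdr = fdr)))
}
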