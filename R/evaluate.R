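# Evaluation of QTL results and inferred covariates against simulation
# truth: AUPRC over (feature, SNP) pairs ranked by p-value, power under a
# significance rule, and adjusted-R^2 concordance between true hidden and
# inferred covariates.

.pairKey <- function(feature, snp) paste(feature, snp, sep = "\r")

#' Area under the precision-recall curve of a QTL result
#'
#' Pairs are ranked by ascending p-value; the precision-recall curve is
#' traced over all thresholds with tied p-values collapsed into single
#' steps, and the area is the step-wise sum of precision at each achieved
#' recall times the recall increment (Davis-Goadrich-consistent; no
#' interpolation). AUPRC suits the heavily imbalanced QTL setting, where
#' negatives vastly outnumber positives. Rows with NA p-values are
#' excluded (count reported via message).
#'
#' @param res a \linkS4class{QTLResultTable}
#' @param truth data.frame of causal pairs with columns feature_id, snp_id;
#'   every truth pair must appear among the tested pairs
#' @return AUPRC in [0, 1]
#' @export
computeAUPRC <- function(res, truth) {
  stopifnot(is(res, "QTLResultTable"), is.data.frame(truth))
  tab <- qtlTable(res)
  keyT <- .pairKey(truth$feature_id, truth$snp_id)
  keyA <- .pairKey(tab$feature_id, tab$snp_id)
  if (!all(keyT %in% keyA)) stop("some truth pairs were not tested")
  drop <- is.na(tab$p_value)
  if (any(drop)) {
    message("computeAUPRC: excluding ", sum(drop), " pair(s) with NA p-values")
    tab <- tab[!drop, , drop = FALSE]
    keyA <- keyA[!drop]
  }
  lab <- keyA %in% keyT
  npos <- sum(lab)
  if (npos == 0L) stop("no positive pairs among tested pairs")
  if (npos == length(lab)) stop("no negative pairs among tested pairs")
  o <- order(tab$p_value)
  p <- tab$p_value[o]
  lab <- lab[o]
  # collapse tied p-values into single threshold steps
  newThr <- which(!duplicated(p))
  stepEnd <- c(newThr[-1L] - 1L, length(p))
  cumTP <- cumsum(lab)[stepEnd]
  cumAll <- stepEnd
  prec <- cumTP / cumAll
  rec <- cumTP / npos
  sum(diff(c(0, rec)) * prec)
}

#' Power of a QTL result on the true pairs
#'
#' Fraction of ground-truth causal pairs called significant under the
#' rule: either `list(bh_fdr = 0.05)` (q-value from the emitted table at
#' or below the threshold) or `list(nominal_p = alpha)`.
#'
#' @param res a \linkS4class{QTLResultTable}
#' @param truth data.frame with feature_id, snp_id
#' @param rule named list with element `bh_fdr` or `nominal_p`
#' @return power in [0, 1]
#' @export
computePower <- function(res, truth, rule = list(bh_fdr = 0.05)) {
  stopifnot(is(res, "QTLResultTable"), is.data.frame(truth))
  tab <- qtlTable(res)
  keyT <- .pairKey(truth$feature_id, truth$snp_id)
  keyA <- .pairKey(tab$feature_id, tab$snp_id)
  if (!all(keyT %in% keyA)) stop("some truth pairs were not tested")
  if (!is.null(rule$bh_fdr)) {
    sig <- !is.na(tab$q_value) & tab$q_value <= rule$bh_fdr
  } else if (!is.null(rule$nominal_p)) {
    sig <- !is.na(tab$p_value) & tab$p_value <= rule$nominal_p
  } else stop("rule must name bh_fdr or nominal_p")
  sum(keyT %in% keyA[sig]) / length(keyT)
}

#' Concordance between true hidden and inferred covariates
#'
#' Regresses each true hidden covariate on the full inferred set (m
#' adjusted R^2's) and each inferred covariate on the full true hidden set
#' (n reverse adjusted R^2's), using OLS with intercept and the standard
#' small-sample adjustment 1 - (1 - R^2)(N - 1)/(N - k - 1). The adjusted
#' R^2 score and reverse adjusted R^2 score are the two means; the
#' concordance score is their average. All three are invariant to
#' per-column affine maps, column permutation and sign flips of either
#' set.
#'
#' @param trueHidden \linkS4class{CovariateMatrix} (m columns, m >= 1)
#' @param inferred \linkS4class{CovariateMatrix} (n_inf columns, >= 1)
#' @return list(adj_r2_score, rev_adj_r2_score, concordance)
#' @export
concordanceScores <- function(trueHidden, inferred) {
  stopifnot(is(trueHidden, "CovariateMatrix"), is(inferred, "CovariateMatrix"))
  .checkSampleAlignment(trueHidden, inferred, "true and inferred covariates")
  Tv <- as.matrix(trueHidden)
  Iv <- as.matrix(inferred)
  m <- ncol(Tv); ni <- ncol(Iv); N <- nrow(Tv)
  if (m < 1L || ni < 1L) stop("need at least one covariate on each side")
  if (max(m, ni) >= N - 1L)
    stop("covariates >= samples - 1: adjusted R^2 undefined")
  adj <- vapply(seq_len(m), function(j) .olsAdjR2(Tv[, j], Iv), numeric(1L))
  rev <- vapply(seq_len(ni), function(j) .olsAdjR2(Iv[, j], Tv), numeric(1L))
  a <- mean(adj); r <- mean(rev)
  list(adj_r2_score = a, rev_adj_r2_score = r, concordance = (a + r) / 2)
}

#' Evaluate one QTL run against simulation truth
#'
#' Bundles [computeAUPRC()], [computePower()] and (when an inferred
#' covariate set is supplied) [concordanceScores()].
#'
#' @param res a \linkS4class{QTLResultTable}
#' @param truth data.frame of causal pairs
#' @param trueHidden,inferred optional covariate matrices for the
#'   concordance metrics
#' @param rule significance rule for power (see [computePower()])
#' @return list with auprc, power, adj_r2_score, rev_adj_r2_score,
#'   concordance (NA when not applicable), m_pairs, tested_pairs, rule
#' @export
evaluateRun <- function(res, truth, trueHidden = NULL, inferred = NULL,
                        rule = list(bh_fdr = 0.05)) {
  out <- list(auprc = computeAUPRC(res, truth),
              power = computePower(res, truth, rule),
              adj_r2_score = NA_real_, rev_adj_r2_score = NA_real_,
              concordance = NA_real_,
              m_pairs = nrow(truth), tested_pairs = nrow(qtlTable(res)),
              rule = rule)
  if (!is.null(trueHidden) && !is.null(inferred) &&
      ncol(as.matrix(trueHidden)) >= 1L && ncol(as.matrix(inferred)) >= 1L) {
    cs <- concordanceScores(trueHidden, inferred)
    out$adj_r2_score <- cs$adj_r2_score
    out$rev_adj_r2_score <- cs$rev_adj_r2_score
    out$concordance <- cs$concordance
  }
  out
}
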