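# Benchmark engine: simulate over a parameter grid, run each
# covariate-handling method through the QTL engine, and score it.

.cbindCovariates <- function(a, b, role = "inferred") {
  av <- if (is.null(a)) NULL else as.matrix(a)
  bv <- if (is.null(b)) NULL else as.matrix(b)
  if (is.null(av) || ncol(av) == 0L) v <- bv
  else if (is.null(bv) || ncol(bv) == 0L) v <- av
  else v <- cbind(av, bv)
  new("CovariateMatrix", values = v, role = role)
}

# Resolve the number of components for a method on one dataset.
.resolveK <- function(kPolicy, sim, pcaRes, seed) {
  if (is.numeric(kPolicy)) return(as.integer(kPolicy))
  switch(kPolicy,
    true = max(1L, ncol(as.matrix(hiddenCovariates(sim)))),
    elbow = max(1L, selectedK(selectKElbow(pve(pcaRes)))),
    be = max(1L, selectedK(selectKBE(simPhenotypes(sim), seed = seed))),
    stop("unknown K policy: ", kPolicy))
}

#' Run the simulation benchmark over a parameter grid
#'
#' For every grid cell and replicate, simulates a dataset, runs each
#' method's covariate inference, maps cis-QTLs with the resulting
#' covariates, and scores the run (AUPRC, power, adjusted-R^2 concordance
#' where an inferred set exists). Methods:
#' \describe{
#'   \item{ideal}{known + true hidden covariates (the oracle upper bound)}
#'   \item{unadjusted}{known covariates only}
#'   \item{pca_direct}{top PCs of the phenotypes + filtered known covariates}
#'   \item{pca_resid}{top PCs after regressing out the known covariates +
#'     all known covariates}
#'   \item{hcp}{HCP components + all known covariates (needs K1 >= 1)}
#'   \item{external:<path>}{a user-supplied inferred covariate TSV (how
#'     externally computed factor matrices plug in) + filtered known
#'     covariates}
#' }
#'
#' @param base a [simParams()] list: the cell-independent settings
#' @param grid named list mapping a simParams field to a vector of levels;
#'   empty list = a single cell at `base`
#' @param replicates replicate datasets per cell
#' @param methods character vector drawn from the list above
#' @param seed master seed; every cell x replicate derives its own stream
#' @param kPolicy "true" (number of hidden covariates), "elbow", "be", or
#'   a fixed integer
#' @param fdr BH threshold for the power metric
#' @param hcpLambdas penalty weights for the HCP runs
#' @return long-format data.frame: one row per cell x replicate x method
#'   with the grid levels, auprc, power, adj_r2, rev_adj_r2, concordance,
#'   K and runtime_s
#' @export
benchmarkGrid <- function(base, grid = list(), replicates = 2L, methods,
                          seed = 1L, kPolicy = "true", fdr = 0.05,
                          hcpLambdas = c(1, 1, 1)) {
  stopifnot(inherits(base, "simParams"))
  known <- c("ideal", "unadjusted", "pca_direct", "pca_resid", "hcp")
  bad <- methods[!(methods %in% known | startsWith(methods, "external:"))]
  if (length(bad)) stop("unknown method name(s): ", paste(bad, collapse = ", "))
  cells <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
           else data.frame(row.names = 1L)
  rows <- list()
  for (ci in seq_len(max(1L, nrow(cells)))) {
    cellParams <- unclass(base)
    if (ncol(cells)) for (ax in names(cells)) cellParams[[ax]] <- cells[ci, ax]
    for (rep in seq_len(replicates)) {
      repSeed <- deriveSeed(seed, sprintf("cell%03d_rep%03d", ci, rep))
      cellParams$seed <- repSeed
      params <- do.call(simParams, cellParams[setdiff(names(cellParams), character(0))])
      sim <- simulateQTLData(params)
      Y <- simPhenotypes(sim); G <- simGenotypes(sim)
      X1 <- knownCovariates(sim); X2 <- hiddenCovariates(sim)
      truthCis <- truePairs(sim)
      truthCis <- truthCis[truthCis$type == "cis", , drop = FALSE]
      pcaCache <- NULL
      for (method in methods) {
        t0 <- proc.time()[["elapsed"]]
        inferred <- NULL
        K <- NA_integer_
        if (method == "ideal") {
          X <- .cbindCovariates(X1, X2, role = "known")
        } else if (method == "unadjusted") {
          X <- X1
        } else if (method %in% c("pca_direct", "pca_resid")) {
          if (is.null(pcaCache)) pcaCache <- runPCA(Y, center = TRUE, scale = TRUE)
          K <- .resolveK(kPolicy, sim, pcaCache,
                         deriveSeed(repSeed, paste0("be_", method)))
          inf <- inferCovariates(Y, X1, variant = method, K = K)
          inferred <- inf$inferred
          X <- .cbindCovariates(inf$knownUsed, inferred)
        } else if (method == "hcp") {
          if (ncol(as.matrix(X1)) == 0L)
            stop("method 'hcp' requires known covariates (K1 >= 1)")
          if (is.null(pcaCache)) pcaCache <- runPCA(Y, center = TRUE, scale = TRUE)
          K <- .resolveK(kPolicy, sim, pcaCache, deriveSeed(repSeed, "be_hcp"))
          fit <- fitHCP(transformPhenotypes(Y, "center_scale"), X1, K = K,
                        lambdas = hcpLambdas)
          inferred <- new("CovariateMatrix", values = hiddenComponents(fit),
                          role = "inferred")
          X <- .cbindCovariates(X1, inferred)
        } else { # external:<path>
          path <- sub("^external:", "", method)
          inferred <- readCovariates(path, role = "inferred")
          inferred <- new("CovariateMatrix",
                          values = as.matrix(inferred)[sampleIDs(Y), , drop = FALSE],
                          role = "inferred")
          keptX1 <- if (ncol(as.matrix(X1)) > 0L)
            filterKnownCovariates(X1, inferred)$kept else X1
          X <- .cbindCovariates(keptX1, inferred)
        }
        tInfer <- proc.time()[["elapsed"]] - t0
        res <- mapQTL(Y, G, X, scope = "cis")
        ev <- evaluateRun(res, truthCis,
                          trueHidden = if (!is.null(inferred)) X2 else NULL,
                          inferred = inferred, rule = list(bh_fdr = fdr))
        row <- data.frame(cell = ci, replicate = rep, method = method,
                          auprc = ev$auprc, power = ev$power,
                          adj_r2 = ev$adj_r2_score,
                          rev_adj_r2 = ev$rev_adj_r2_score,
                          concordance = ev$concordance,
                          K = K, runtime_s = tInfer,
                          stringsAsFactors = FALSE)
        if (ncol(cells))
          row <- cbind(row, cells[ci, , drop = FALSE], row.names = NULL)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
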