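# End-to-end orchestration: the recommended inference workflow
# (transform -> PCA -> choose K -> filter known covariates) and the
# benchmark workflow, with YAML/list configs and a JSON run manifest.

.fileDigest <- function(path) unname(tools::md5sum(path))

.readConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.newManifest <- function(config, seed) {
  list(package_version = as.character(utils::packageVersion("pcaqtl")),
       config = config, master_seed = seed,
       inputs = list(), outputs = list(), timings = list(), stages = character(0))
}

.manifestStage <- function(manifest, name, t0) {
  manifest$stages <- c(manifest$stages, name)
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  manifest
}

#' Run the recommended covariate-inference workflow
#'
#' Stages: read (or accept) the phenotype and known-covariate inputs,
#' transform the phenotypes, run PCA, choose K (fixed / elbow / BE),
#' assemble the inferred covariates (filtering known covariates under
#' pca_direct), and optionally write the merged covariate table ready for
#' [mapQTL()] plus a JSON manifest recording config, seeds, digests and
#' timings.
#'
#' Config fields (list or YAML path): `phenotypes` (path or
#' PhenotypeMatrix), `phenotype_format` ("tsv"/"bed"), `orientation`,
#' `known_covariates` (path or CovariateMatrix, optional), `transform`
#' (default "center_scale"), `variant` ("pca_direct" default /
#' "pca_resid"), `k_policy` (list(method = "fixed", k = ...) or
#' list(method = "elbow") or list(method = "be", B = , alpha = )),
#' `r2_threshold` (default 0.9), `seed`, `output_dir` (optional).
#'
#' @param config list or path to a YAML file
#' @return list(inferred, knownUsed, kSelection, pca, manifest)
#' @export
runInference <- function(config) {
  config <- .readConfig(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- .newManifest(config[!vapply(config, is.object, logical(1L))], seed)
  t0 <- proc.time()[["elapsed"]]

  # --- read
  Y <- config$phenotypes
  if (is.character(Y)) {
    manifest$inputs$phenotypes <- list(path = Y, md5 = .fileDigest(Y))
    Y <- readPhenotypes(Y, format = if (is.null(config$phenotype_format)) "tsv"
                        else config$phenotype_format,
                        orientation = if (is.null(config$orientation))
                          "samples_by_features" else config$orientation)
  }
  stopifnot(is(Y, "PhenotypeMatrix"))
  X1 <- config$known_covariates
  if (is.character(X1)) {
    manifest$inputs$known_covariates <- list(path = X1, md5 = .fileDigest(X1))
    X1 <- readCovariates(X1, role = "known")
  }
  if (!is.null(X1)) {
    al <- alignSamples(Y, X1)
    Y <- al$Y; X1 <- al$X
  }
  manifest <- .manifestStage(manifest, "read", t0)

  # --- transform
  t0 <- proc.time()[["elapsed"]]
  tf <- if (is.null(config$transform)) "center_scale" else config$transform
  Yt <- transformPhenotypes(Y, method = tf)
  manifest <- .manifestStage(manifest, "transform", t0)

  # --- PCA
  t0 <- proc.time()[["elapsed"]]
  variant <- if (is.null(config$variant)) "pca_direct" else config$variant
  pcaFull <- if (variant == "pca_direct") runPCA(Yt, center = TRUE, scale = TRUE)
             else runPCA(regressOut(Yt, X1), center = TRUE, scale = TRUE)
  manifest <- .manifestStage(manifest, "pca", t0)

  # --- choose K
  t0 <- proc.time()[["elapsed"]]
  kp <- if (is.null(config$k_policy)) list(method = "be") else config$k_policy
  ksel <- switch(kp$method,
    fixed = new("KSelection", method = "elbow", K = as.integer(kp$k),
                diagnostics = data.frame(component = seq_along(pve(pcaFull)),
                                         pve = pve(pcaFull),
                                         distance = NA_real_),
                params = list(policy = "fixed"), seed = NULL),
    elbow = selectKElbow(pve(pcaFull)),
    be = selectKBE(Yt,
                   B = if (is.null(kp$B)) 20L else kp$B,
                   alpha = if (is.null(kp$alpha)) 0.05 else kp$alpha,
                   seed = deriveSeed(seed, "be")),
    stop("unknown K policy method: ", kp$method))
  K <- max(1L, selectedK(ksel))
  manifest$K <- K
  manifest$k_method <- kp$method
  manifest <- .manifestStage(manifest, "choose_k", t0)

  # --- assemble covariates
  t0 <- proc.time()[["elapsed"]]
  r2thr <- if (is.null(config$r2_threshold)) 0.9 else config$r2_threshold
  inf <- inferCovariates(Yt, X1, variant = variant, K = K,
                         r2Threshold = r2thr)
  manifest <- .manifestStage(manifest, "infer", t0)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    merged <- .cbindCovariates(inf$knownUsed, inf$inferred)
    covPath <- file.path(config$output_dir, "covariates_merged.tsv")
    writeCovariates(merged, covPath)
    pvePath <- file.path(config$output_dir, "pve.tsv")
    utils::write.table(data.frame(component = seq_along(pve(inf$pca)),
                                  pve = pve(inf$pca)),
                       pvePath, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <- list(
      covariates_merged = list(path = covPath, md5 = .fileDigest(covPath)),
      pve = list(path = pvePath, md5 = .fileDigest(pvePath)))
    manPath <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  list(inferred = inf$inferred, knownUsed = inf$knownUsed, kSelection = ksel,
       pca = inf$pca, manifest = manifest)
}

#' Run the benchmark workflow from a config
#'
#' Delegates to [benchmarkGrid()] and optionally writes the long-format
#' result TSV plus a JSON manifest. Config fields: `base` (named list of
#' [simParams()] overrides), `grid` (named list of axis levels),
#' `replicates`, `methods`, `k_policy`, `fdr`, `seed`, `out` (optional
#' output TSV path).
#'
#' @param config list or path to a YAML file
#' @return list(results = data.frame, manifest = list)
#' @export
runBenchmark <- function(config) {
  config <- .readConfig(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- .newManifest(config, seed)
  t0 <- proc.time()[["elapsed"]]
  base <- do.call(simParams, c(config$base, list()))
  res <- benchmarkGrid(base,
                       grid = if (is.null(config$grid)) list() else config$grid,
                       replicates = if (is.null(config$replicates)) 2L
                                    else config$replicates,
                       methods = config$methods, seed = seed,
                       kPolicy = if (is.null(config$k_policy)) "true"
                                 else config$k_policy,
                       fdr = if (is.null(config$fdr)) 0.05 else config$fdr)
  manifest <- .manifestStage(manifest, "benchmark", t0)
  if (!is.null(config$out)) {
    dir.create(dirname(config$out), showWarnings = FALSE, recursive = TRUE)
    # timings are not reproducible across runs; they stay in the returned
    # table and the manifest, not in the on-disk results file
    utils::write.table(res[setdiff(names(res), "runtime_s")], config$out,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <- list(results = list(path = config$out,
                                            md5 = .fileDigest(config$out)))
    manPath <- paste0(config$out, ".manifest.json")
    jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  list(results = res, manifest = manifest)
}
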