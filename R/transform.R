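# Phenotype transforms applied before hidden-variable inference:
# center/scale, and rank-based inverse normal transforms applied within
# feature or within sample.

#' Rank-based inverse normal transform
#'
#' Maps a numeric vector to standard normal quantiles of its ranks using
#' the Blom offset: qnorm((rank - 3/8) / (n + 1/4)). Ties receive average
#' ranks, hence equal transformed values. The result depends on the input
#' only through its ranks, so any strictly monotone transform of the input
#' leaves it unchanged.
#'
#' @param x numeric vector
#' @return numeric vector of normal scores
#' @export
inverseNormalTransform <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Transform a phenotype matrix
#'
#' Available methods: `none` (identity), `center_scale` (each feature to
#' mean 0, sd 1, n-1 denominator), `int_within_feature` (inverse normal
#' transform of each feature column), `int_within_sample` (inverse normal
#' transform of each sample row).
#'
#' @param Y a \linkS4class{PhenotypeMatrix}
#' @param method one of "none", "center_scale", "int_within_feature",
#'   "int_within_sample"
#' @return a transformed \linkS4class{PhenotypeMatrix}
#' @export
transformPhenotypes <- function(Y, method = c("none", "center_scale",
                                              "int_within_feature",
                                              "int_within_sample")) {
  stopifnot(is(Y, "PhenotypeMatrix"))
  method <- match.arg(method)
  v <- as.matrix(Y)
  out <- switch(method,
    none = v,
    center_scale = .centerScale(v, center = TRUE, scale = TRUE),
    int_within_feature = apply(v, 2L, inverseNormalTransform),
    int_within_sample = t(apply(v, 1L, inverseNormalTransform))
  )
  dimnames(out) <- dimnames(v)
  PhenotypeMatrix(out, featureCoords = featureCoords(Y))
}
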