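#' Principal component summary of a methylation cohort
#'
#' Column-centered PCA of the samples on the beta scale. CpGs with missing
#' values are mean-imputed per CpG before decomposition.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param n_components Number of components to return; truncated to the
#'   matrix rank with a message when too many are requested.
#' @return List with `scores` (samples x components) and `var_frac`, the
#'   non-increasing fractions of total variance per component.
#' @export
pca_summary <- function(beta, n_components = 10L) {
  stopifnot(ncol(beta) >= 2)
  b <- beta
  if (anyNA(b)) {
    mu <- rowMeans(b, na.rm = TRUE)
    idx <- which(is.na(b), arr.ind = TRUE)
    b[idx] <- mu[idx[, 1]]
  }
  pc <- stats::prcomp(t(b), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (n_components > rank) {
    message("requested ", n_components, " components; rank is ", rank)
    n_components <- rank
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       var_frac = var_frac[seq_len(n_components)])
}

#' Most-variable CpGs and sample clustering order
#'
#' Ranks CpGs by variance across samples, takes the top `n`, clusters samples
#' on that subset (Euclidean distance, average linkage) and returns the
#' dendrogram leaf order — the layout of a top-variable-CpG heatmap.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param n Number of top-variable CpGs, default 1000; capped at the probe
#'   count with a warning.
#' @return List with `cpgs` (selected probe ids, by decreasing variance),
#'   `order` (sample ids in leaf order) and `hclust`, the clustering object.
#' @export
top_variable_order <- function(beta, n = 1000L) {
  if (n > nrow(beta)) {
    warning("n exceeds the number of CpGs; using all ", nrow(beta))
    n <- nrow(beta)
  }
  v <- row_sds(beta)^2
  top <- order(v, decreasing = TRUE)[seq_len(n)]
  sub <- beta[top, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(sub)), method = "average")
  list(cpgs = rownames(beta)[top],
       order = colnames(beta)[hc$order],
       hclust = hc)
}
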