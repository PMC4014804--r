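#' Pearson correlation with degenerate-input guard
#'
#' Product-moment correlation between paired observations; pairs with missing
#' values are dropped. Returns `NA` with a warning when fewer than 3 complete
#' pairs remain or either variable has zero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Pearson r, or `NA`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("fewer than 3 complete pairs or zero variance; r undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# all permutations of 1..n (n <= 7), one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Permutation p-value for a methylation-expression correlation
#'
#' Compares the observed |Pearson r| to its distribution under random
#' permutation of the expression values. For 7 or fewer samples every
#' permutation is enumerated; otherwise `B` random permutations are drawn
#' with the supplied seed. The estimate `p = (1 + #(|r_b| >= |r_obs|)) /
#' (n_perm + 1)` never reaches zero.
#'
#' @param x,y Numeric vectors (e.g. beta-values and log2 expression).
#' @param B Number of random permutations, default 10000 (a warning is issued
#'   below 100).
#' @param seed Integer seed for the permutation draw.
#' @return List with `r` (observed correlation) and `p` (permutation
#'   p-value); both `NA` when the correlation is undefined.
#' @export
permutation_pvalue <- function(x, y, B = 10000, seed = 1L) {
  if (B < 100) warning("B < 100 permutations gives a coarse p-value")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  r_obs <- sum(xc * yc) / denom
  if (n <= 7) {
    perms <- all_permutations(n)
    r_b <- apply(perms, 1L, function(pm) sum(xc * yc[pm]) / denom)
    n_perm <- nrow(perms)
  } else {
    set.seed(seed)
    r_b <- vapply(seq_len(B), function(b) {
      sum(xc * yc[sample.int(n)]) / denom
    }, numeric(1))
    n_perm <- B
  }
  p <- (1 + sum(abs(r_b) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  list(r = r_obs, p = p)
}

#' Correlate signature CpGs with the expression of their annotated genes
#'
#' Builds one row per (CpG, annotated gene) pair for which expression data
#' exist, computes the Pearson correlation between beta-values and log2
#' expression across the shared samples, a permutation p-value, BH adjustment
#' over the signature's rows, and the linear-scale fold change between the
#' comparison group and the reference samples. A pair is flagged `correlated`
#' when the adjusted permutation p is at most `alpha` and the fold change is
#' at least `min_fold` in either direction.
#'
#' @param signature Data frame with a `probe` column (and optionally
#'   `subtype`), or a character vector of probe ids.
#' @param beta Probe-by-sample beta matrix.
#' @param expression Genes-by-samples log2 expression matrix.
#' @param annotation Probe annotation providing the gene lists.
#' @param sheet Sample sheet; used to define the fold-change contrast.
#' @param group_subtype Subtype whose samples form the comparison group for
#'   the fold change; `NULL` (default) compares all diagnostic ALL samples
#'   with the reference samples, which is the natural contrast for the
#'   constitutive signature.
#' @param B Permutations per pair, default 10000.
#' @param alpha BH-adjusted permutation-p cut-off, default 0.05.
#' @param min_fold Minimum linear fold change, default 2.
#' @param seed Integer seed.
#' @return Data frame of `CorrelationRow`s: `probe`, `gene`, `r`, `p`, `q`,
#'   `fold_change` (2^|difference of group log2 means|, signed by direction),
#'   `correlated`.
#' @export
correlate_signature <- function(signature, beta, expression, annotation,
                                sheet, group_subtype = NULL, B = 10000,
                                alpha = 0.05, min_fold = 2, seed = 1L) {
  probes <- if (is.data.frame(signature)) signature$probe else signature
  probes <- intersect(probes, rownames(beta))
  shared <- intersect(colnames(beta), colnames(expression))
  if (length(shared) < 3) stop("fewer than 3 samples shared by beta and expression")

  genes_of <- strsplit(annotation$UCSC_RefGene_Name[
    match(probes, annotation$IlmnID)], ";", fixed = TRUE)
  pairs <- do.call(rbind, lapply(seq_along(probes), function(i) {
    g <- unique(genes_of[[i]])
    g <- g[!is.na(g) & g != ""]
    g <- intersect(g, rownames(expression))
    if (!length(g)) return(NULL)
    data.frame(probe = probes[i], gene = g, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || !nrow(pairs)) {
    return(data.frame(probe = character(0), gene = character(0),
                      r = numeric(0), p = numeric(0), q = numeric(0),
                      fold_change = numeric(0), correlated = logical(0)))
  }

  grp_ids <- if (is.null(group_subtype)) {
    sheet$sample_id[sheet$role == "ALL" & sheet$phase == "diagnosis"]
  } else {
    sheet$sample_id[sheet$role == "ALL" & sheet$phase == "diagnosis" &
                      sheet$subtype == group_subtype]
  }
  ref_ids <- sheet$sample_id[sheet$role == "reference"]
  grp_ids <- intersect(grp_ids, shared)
  ref_ids <- intersect(ref_ids, shared)

  res <- lapply(seq_len(nrow(pairs)), function(k) {
    x <- beta[pairs$probe[k], shared]
    y <- expression[pairs$gene[k], shared]
    pv <- permutation_pvalue(x, y, B = B, seed = seed + k)
    lfc <- if (length(grp_ids) && length(ref_ids)) {
      mean(expression[pairs$gene[k], grp_ids]) -
        mean(expression[pairs$gene[k], ref_ids])
    } else NA_real_
    c(r = pv$r, p = pv$p, lfc = lfc)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    probe = pairs$probe, gene = pairs$gene,
    r = res[, "r"], p = res[, "p"],
    q = bh_adjust(res[, "p"]),
    fold_change = sign(res[, "lfc"]) * 2^abs(res[, "lfc"]),
    stringsAsFactors = FALSE
  )
  out$correlated <- !is.na(out$q) & out$q <= alpha &
    !is.na(out$fold_change) & abs(out$fold_change) >= min_fold
  out
}
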