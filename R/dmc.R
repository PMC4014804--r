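#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two independent groups of beta-values. The p-value is exact
#' (distribution of the rank-sum statistic) when the combined sample size is
#' at most 25 and there are no ties; otherwise a normal approximation with tie
#' and continuity correction is used. Groups whose pooled values are all
#' identical yield p = 1.
#'
#' @param group_a,group_b Numeric vectors with at least 2 non-missing values
#'   each.
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (length(unique(c(a, b))) == 1L) return(1)
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0L
  suppressWarnings(
    stats::wilcox.test(a, b, exact = (n <= 25 && !ties), correct = TRUE)$p.value
  )
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Used for the diagnosis-versus-relapse comparison: the input is the vector
#' of per-patient differences. Zero differences are dropped. Exact p when at
#' most 25 non-zero differences with untied magnitudes, else normal
#' approximation with tie and continuity correction.
#'
#' @param diffs Numeric vector of paired differences with at least 5 non-zero
#'   values.
#' @return Two-sided p-value; 1 when all differences are zero.
#' @export
signed_rank_test <- function(diffs) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  if (length(d) < 5L) stop("need at least 5 non-zero paired differences")
  ties <- anyDuplicated(abs(d)) > 0L
  suppressWarnings(
    stats::wilcox.test(d, exact = (length(d) <= 25 && !ties), correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; a thin wrapper around [stats::p.adjust()] that
#' preserves missing values and input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Reference-variability filter
#'
#' CpG sites whose standard deviation across the pooled reference samples
#' exceeds the threshold reflect normal cell-type variability rather than
#' leukemia-associated change and are excluded from DMC lists. The boundary is
#' strict: SD exactly equal to the threshold is kept.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param reference_ids Sample ids (columns of `beta`) forming the reference
#'   panel; at least 2.
#' @param threshold SD cut-off, default 0.10.
#' @return Character vector of excluded probe ids.
#' @export
reference_sd_filter <- function(beta, reference_ids, threshold = 0.10) {
  stopifnot(length(reference_ids) >= 2, all(reference_ids %in% colnames(beta)))
  sds <- row_sds(beta[, reference_ids, drop = FALSE])
  rownames(beta)[!is.na(sds) & sds > threshold]
}

row_sds <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - mu)^2, na.rm = TRUE)
  out <- sqrt(ss / (n - 1))
  out[n < 2] <- NA_real_
  out
}

# Row-wise two-sided rank-sum p-values, reproducing stats::wilcox.test's rules:
# exact rank-sum distribution when nA+nB <= 25 and the row has no ties, else
# normal approximation with tie and continuity correction.
row_ranksum_p <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  n <- na + nb
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  apply(sub, 1L, function(v) {
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (length(unique(c(a, b))) == 1L) return(1)
    r <- rank(c(a, b))
    nx <- length(a); ny <- length(b); nn <- nx + ny
    w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    tie_tab <- table(r)
    ties <- any(tie_tab > 1)
    if (nn <= 25 && !ties) {
      p <- if (w > nx * ny / 2) {
        stats::pwilcox(w - 1, nx, ny, lower.tail = FALSE)
      } else {
        stats::pwilcox(w, nx, ny)
      }
      return(min(2 * p, 1))
    }
    z <- w - nx * ny / 2
    sigma <- sqrt((nx * ny / 12) *
                    ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))))
    if (sigma == 0) return(1)
    z <- (z - sign(z) * 0.5) / sigma
    min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
  })
}

# Row-wise two-sided signed-rank p on paired difference matrix (rows = CpGs).
row_signedrank_p <- function(diff_mat) {
  apply(diff_mat, 1L, function(d) {
    d <- d[!is.na(d)]
    d <- d[d != 0]
    nz <- length(d)
    if (nz == 0L) return(1)
    if (nz < 5L) return(NA_real_)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    tie_tab <- table(r)
    ties <- any(tie_tab > 1)
    if (nz <= 25 && !ties) {
      p <- if (v > nz * (nz + 1) / 4) {
        stats::psignrank(v - 1, nz, lower.tail = FALSE)
      } else {
        stats::psignrank(v, nz)
      }
      return(min(2 * p, 1))
    }
    z <- v - nz * (nz + 1) / 4
    sigma <- sqrt(nz * (nz + 1) * (2 * nz + 1) / 24 -
                    sum(tie_tab^3 - tie_tab) / 48)
    if (sigma == 0) return(1)
    z <- (z - sign(z) * 0.5) / sigma
    min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
  })
}

reference_panel_types <- function(lineage) {
  switch(lineage,
         B = c("BM", "CD19", "CD34"),
         T = c("BM", "CD3", "CD34"),
         stop("unknown lineage: ", lineage))
}

#' Call differentially methylated CpG sites for one ALL subtype
#'
#' Tests every retained CpG for a methylation difference between the
#' diagnostic samples of one subtype and the lineage-matched non-leukemic
#' reference panel (BM, CD19+ and CD34+ cells for B-cell-precursor ALL; BM,
#' CD3+ and CD34+ cells for T-ALL) with the Wilcoxon rank-sum test. A site is
#' flagged as a DMC when the BH-adjusted p is below `fdr`, the absolute mean
#' beta difference is at least `delta_beta`, and the pooled reference SD does
#' not exceed `ref_sd`.
#'
#' @param beta Probe-by-sample beta matrix (typically peak-corrected and
#'   filtered).
#' @param sheet Sample sheet as returned by [read_sheet()] /
#'   [simulate_cohort()].
#' @param subtype Subtype label to test; must appear in `sheet$subtype`.
#' @param delta_beta Minimum absolute mean beta difference, default 0.2.
#' @param fdr BH-adjusted p cut-off, default 0.01.
#' @param ref_sd Reference-panel SD cut-off, default 0.10; set
#'   `apply_sd_filter = FALSE` to disable.
#' @param apply_sd_filter Apply the reference-variability gate (default TRUE).
#' @return A `DmcTable` data frame with one row per tested CpG: `probe`,
#'   `delta_beta` (subtype mean minus reference mean), `p`, `q`, `ref_sd`,
#'   `direction` (`"hyper"`/`"hypo"`), and `is_dmc`.
#' @export
call_dmcs <- function(beta, sheet, subtype,
                      delta_beta = 0.2, fdr = 0.01, ref_sd = 0.10,
                      apply_sd_filter = TRUE) {
  known <- sort(unique(sheet$subtype[sheet$role == "ALL"]))
  if (!subtype %in% known) {
    stop("unknown subtype '", subtype, "'; valid subtypes: ",
         paste(known, collapse = ", "))
  }
  sub_rows <- sheet$role == "ALL" & sheet$subtype == subtype &
    sheet$phase == "diagnosis"
  lineage <- unique(sheet$lineage[sub_rows])
  lineage <- lineage[!is.na(lineage)][1]
  panel <- reference_panel_types(lineage)
  ref_rows <- sheet$role == "reference" & sheet$cell_type %in% panel
  sub_ids <- intersect(sheet$sample_id[sub_rows], colnames(beta))
  ref_ids <- intersect(sheet$sample_id[ref_rows], colnames(beta))
  if (length(ref_ids) == 0) stop("reference panel is empty for lineage ", lineage)
  if (length(sub_ids) < 2) stop("fewer than 2 samples for subtype ", subtype)

  idx_a <- match(sub_ids, colnames(beta))
  idx_b <- match(ref_ids, colnames(beta))
  mean_a <- rowMeans(beta[, idx_a, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(beta[, idx_b, drop = FALSE], na.rm = TRUE)
  db <- mean_a - mean_b
  p <- row_ranksum_p(beta, idx_a, idx_b)
  q <- bh_adjust(p)
  rsd <- row_sds(beta[, idx_b, drop = FALSE])
  sd_ok <- if (apply_sd_filter) !is.na(rsd) & rsd <= ref_sd else TRUE
  is_dmc <- !is.na(q) & q < fdr & abs(db) >= delta_beta & sd_ok
  data.frame(
    probe = rownames(beta),
    subtype = subtype,
    delta_beta = db,
    p = p,
    q = q,
    ref_sd = rsd,
    direction = ifelse(db > 0, "hyper", "hypo"),
    is_dmc = is_dmc,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call relapse-associated DMCs from paired diagnosis/relapse samples
#'
#' Applies the Wilcoxon signed-rank test to per-patient differences
#' (first relapse minus diagnosis) at every CpG, with the same effect-size,
#' FDR and reference-variability gates as the subtype comparisons. Only first
#' relapse samples enter the paired test. The reference-variability gate pools
#' all reference samples regardless of lineage.
#'
#' @inheritParams call_dmcs
#' @return A `DmcTable` data frame (see [call_dmcs()]); `delta_beta` is the
#'   mean paired difference, relapse minus diagnosis.
#' @export
call_relapse_dmcs <- function(beta, sheet,
                              delta_beta = 0.2, fdr = 0.01, ref_sd = 0.10,
                              apply_sd_filter = TRUE) {
  dg <- sheet[sheet$phase == "diagnosis" & sheet$role == "ALL", ]
  rl <- sheet[sheet$phase == "relapse1", ]
  patients <- intersect(dg$patient_id, rl$patient_id)
  if (length(patients) < 5) stop("need at least 5 diagnosis-relapse pairs")
  d_ids <- dg$sample_id[match(patients, dg$patient_id)]
  r_ids <- rl$sample_id[match(patients, rl$patient_id)]
  stopifnot(all(c(d_ids, r_ids) %in% colnames(beta)))
  diff_mat <- beta[, r_ids, drop = FALSE] - beta[, d_ids, drop = FALSE]
  db <- rowMeans(diff_mat, na.rm = TRUE)
  p <- row_signedrank_p(diff_mat)
  q <- bh_adjust(p)
  ref_ids <- intersect(sheet$sample_id[sheet$role == "reference"], colnames(beta))
  rsd <- if (length(ref_ids) >= 2) {
    row_sds(beta[, ref_ids, drop = FALSE])
  } else {
    rep(NA_real_, nrow(beta))
  }
  sd_ok <- if (apply_sd_filter && length(ref_ids) >= 2) {
    !is.na(rsd) & rsd <= ref_sd
  } else TRUE
  is_dmc <- !is.na(q) & q < fdr & abs(db) >= delta_beta & sd_ok
  data.frame(
    probe = rownames(beta),
    subtype = "relapse",
    delta_beta = db,
    p = p,
    q = q,
    ref_sd = rsd,
    direction = ifelse(db > 0, "hyper", "hypo"),
    is_dmc = is_dmc,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Assemble constitutive and subtype-unique DMC signatures
#'
#' The constitutive signature contains CpGs called as DMCs in every supplied
#' subtype comparison with a consistent direction; the subtype-unique
#' signatures contain CpGs called in exactly one comparison.
#'
#' @param tables Named list of `DmcTable`s from [call_dmcs()], one per
#'   subtype; at least 2.
#' @param require_direction Require the same hyper/hypo direction in every
#'   comparison for constitutive membership (default TRUE).
#' @return List with `constitutive` (data frame `probe`, `direction`) and
#'   `unique` (data frame `probe`, `subtype`, `direction`).
#' @export
build_signatures <- function(tables, require_direction = TRUE) {
  if (length(tables) < 2) stop("need at least 2 subtype comparisons")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("'tables' must be a named list")
  }
  dmc_sets <- lapply(tables, function(t) t$probe[t$is_dmc])
  dir_of <- lapply(tables, function(t) {
    stats::setNames(t$direction[t$is_dmc], t$probe[t$is_dmc])
  })
  all_ids <- unique(unlist(dmc_sets))
  count <- vapply(all_ids, function(id) {
    sum(vapply(dmc_sets, function(s) id %in% s, logical(1)))
  }, integer(1))

  const_ids <- all_ids[count == length(tables)]
  if (require_direction && length(const_ids)) {
    consistent <- vapply(const_ids, function(id) {
      dirs <- vapply(dir_of, function(d) d[[id]], character(1))
      length(unique(dirs)) == 1L
    }, logical(1))
    const_ids <- const_ids[consistent]
  }
  const_dir <- if (length(const_ids)) {
    vapply(const_ids, function(id) dir_of[[1]][[id]], character(1))
  } else character(0)

  uniq_ids <- all_ids[count == 1L]
  uniq <- if (length(uniq_ids)) {
    do.call(rbind, lapply(names(tables), function(nm) {
      ids <- intersect(uniq_ids, dmc_sets[[nm]])
      if (!length(ids)) return(NULL)
      data.frame(probe = ids, subtype = nm,
                 direction = unname(dir_of[[nm]][ids]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(probe = character(0), subtype = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(uniq)) {
    uniq <- data.frame(probe = character(0), subtype = character(0),
                       direction = character(0), stringsAsFactors = FALSE)
  }
  list(
    constitutive = data.frame(probe = const_ids, direction = unname(const_dir),
                              stringsAsFactors = FALSE, row.names = NULL),
    unique = uniq
  )
}
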