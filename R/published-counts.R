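#' Published DMC counts of the NOPHO pediatric ALL 450k cohort
#'
#' Headline differential-methylation counts reported for the NOPHO pediatric
#' ALL cohort (methylation data deposited as GEO series GSE49031): per-subtype
#' total DMCs, annotated gene regions, and the hyper-/hypomethylated split of
#' the subtype-unique DMCs. These serve as worked-example inputs for
#' arithmetic checks; the full cohort itself is far beyond desk scale.
#'
#' @return Data frame with one row per signature: `signature`, `n_patients`,
#'   `dmcs`, `genes`, `genes_unique`, `dmcs_unique`, `unique_hyper`,
#'   `unique_hypo` (NA where not applicable).
#' @export
subtype_dmc_counts <- function() {
  data.frame(
    signature = c("constitutive", "T-ALL", "11q23/MLL", "dic(9;20)", "HeH",
                  "t(1;19)", "t(12;21)", "t(9;22)", "iAMP21", "undefined",
                  "non-recurrent"),
    n_patients = c(774L, 101L, 28L, 20L, 187L, 23L, 163L, 19L, 10L, 105L, 100L),
    dmcs = c(9406L, 58157L, 31403L, 53680L, 42779L, 21799L, 45589L, 23871L,
             44726L, 39262L, 42109L),
    genes = c(2023L, 8245L, 7142L, 9009L, 7773L, 5956L, 7973L, 6047L, 8614L,
              7059L, 7434L),
    genes_unique = c(NA, 895L, 300L, 202L, 271L, 107L, 156L, 36L, 272L, 3L, 2L),
    dmcs_unique = c(NA, 16841L, 1763L, 2370L, 3014L, 1110L, 2114L, 271L,
                    2656L, 56L, 27L),
    unique_hyper = c(NA, 15487L, 1285L, 1561L, 268L, 272L, 1126L, 140L, 997L,
                     8L, 14L),
    unique_hypo = c(NA, 1365L, 478L, 809L, 2746L, 838L, 988L, 131L, 1659L,
                    48L, 13L),
    stringsAsFactors = FALSE
  )
}

#' Percentage split of subtype-unique DMCs by direction
#'
#' Recomputes, from the published hyper-/hypomethylated counts, the
#' percentage of each subtype's unique DMCs that gained or lost methylation
#' relative to the reference panel. Denominator is `unique_hyper +
#' unique_hypo`.
#'
#' @param counts Count table, default [subtype_dmc_counts()].
#' @return Data frame `signature`, `hyper_pct`, `hypo_pct` for rows with
#'   unique-DMC counts.
#' @export
unique_direction_pct <- function(counts = subtype_dmc_counts()) {
  k <- counts[!is.na(counts$unique_hyper), ]
  tot <- k$unique_hyper + k$unique_hypo
  data.frame(signature = k$signature,
             hyper_pct = 100 * k$unique_hyper / tot,
             hypo_pct = 100 * k$unique_hypo / tot,
             stringsAsFactors = FALSE)
}

#' Published relapse-signature set sizes
#'
#' Set sizes of the relapse DMC signature reported for the 27 paired
#' diagnosis/first-relapse samples of the NOPHO cohort: total relapse DMCs
#' and their gene regions, and the overlap with the constitutive signature
#' at the CpG and gene-region level.
#'
#' @return Named list of the four counts.
#' @export
relapse_signature_counts <- function() {
  list(relapse_dmcs = 6612L, relapse_genes = 1854L,
       overlap_constitutive_dmcs = 773L, overlap_constitutive_genes = 1186L)
}

#' Relapse-signature overlap percentages
#'
#' Percentage of relapse DMCs shared with the constitutive signature, and
#' percentage of relapse gene regions shared with the constitutive gene
#' regions, recomputed from the published set sizes.
#'
#' @param counts Set sizes, default [relapse_signature_counts()].
#' @return Named list `dmc_overlap_pct`, `gene_overlap_pct`.
#' @export
relapse_overlap_pct <- function(counts = relapse_signature_counts()) {
  list(dmc_overlap_pct = 100 * counts$overlap_constitutive_dmcs /
         counts$relapse_dmcs,
       gene_overlap_pct = 100 * counts$overlap_constitutive_genes /
         counts$relapse_genes)
}
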