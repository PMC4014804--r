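#' Read a BED file of peaks
#'
#' Minimal BED reader for peak files: the first three columns (chrom, start,
#' end; 0-based half-open) are used, `track`/`browser` header lines and
#' comments are skipped, and chromosome names are normalized by stripping any
#' `chr` prefix.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] of the peaks (1-based closed intervals,
#'   as GRanges represents them).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    return(GenomicRanges::GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad)) {
    stop("malformed BED line ", which(keep)[bad[1]], " in ", path,
         ": fewer than 3 columns")
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    stop("malformed BED line in ", path, ": non-numeric coordinates")
  }
  chrom <- sub("^chr", "", chrom)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0))
}

probe_granges <- function(annotation) {
  chr <- sub("^chr", "", as.character(annotation$CHR))
  GenomicRanges::GRanges(chr, IRanges::IRanges(start = annotation$MAPINFO,
                                               width = 1L))
}

#' Flag probes overlapping replicated chromatin peaks
#'
#' A probe's chromatin-mark flag is set when its single-base position falls
#' inside a peak in at least `min_replicates` of the replicate BED files
#' supplied for that mark. Manifest positions (1-based) and BED intervals
#' (0-based half-open) are reconciled internally.
#'
#' @param annotation Probe annotation data frame with `CHR` and `MAPINFO`.
#' @param peak_files Named list: mark -> character vector of replicate BED
#'   paths.
#' @param min_replicates Minimum number of replicates that must contain the
#'   probe, default 2.
#' @return The annotation with one logical column per mark, plus derived
#'   `bivalent` (H3K4me3 and H3K27me3) and `enhancer` (H3K4me1 and H3K27ac)
#'   columns when their primitives are present.
#' @export
assign_chromatin_marks <- function(annotation, peak_files, min_replicates = 2L) {
  pr <- probe_granges(annotation)
  for (mark in names(peak_files)) {
    hits <- integer(nrow(annotation))
    for (f in peak_files[[mark]]) {
      peaks <- read_bed(f)
      ov <- GenomicRanges::countOverlaps(pr, peaks) > 0
      hits <- hits + as.integer(ov)
    }
    annotation[[mark]] <- hits >= min_replicates
  }
  if (all(c("H3K4me3", "H3K27me3") %in% names(annotation))) {
    annotation$bivalent <- annotation$H3K4me3 & annotation$H3K27me3
  }
  if (all(c("H3K4me1", "H3K27ac") %in% names(annotation))) {
    annotation$enhancer <- annotation$H3K4me1 & annotation$H3K27ac
  }
  annotation
}

#' One-sided Fisher enrichment of a signature in an annotation class
#'
#' Tests whether signature CpGs fall into an annotation class more often than
#' expected from the array background, with the one-sided (greater)
#' hypergeometric p-value. Fold enrichment is the class rate inside the
#' signature divided by the class rate in the background.
#'
#' @param signature Character vector of signature CpG ids (must be a subset of
#'   `background`).
#' @param class_members Character vector of CpG ids belonging to the class.
#' @param background Character vector of all analyzed CpG ids.
#' @return One-row data frame: counts `a` (signature in class), `b`
#'   (signature outside), `c` (non-signature in class), `d` (rest), `fold`,
#'   and one-sided `p`.
#' @export
fisher_enrichment <- function(signature, class_members, background) {
  signature <- unique(signature)
  class_members <- unique(intersect(class_members, background))
  background <- unique(background)
  if (!all(signature %in% background)) {
    stop("signature must be a subset of the background")
  }
  n_sig <- length(signature)
  n_bg <- length(background)
  a <- length(intersect(signature, class_members))
  b <- n_sig - a
  cc <- length(class_members) - a
  dd <- n_bg - n_sig - cc
  if (n_sig == 0L) {
    return(data.frame(a = 0L, b = 0L, c = cc, d = dd,
                      fold = NA_real_, p = NA_real_))
  }
  fold <- (a / n_sig) / ((a + cc) / n_bg)
  p <- stats::phyper(a - 1L, a + cc, n_bg - (a + cc), n_sig,
                     lower.tail = FALSE)
  data.frame(a = a, b = b, c = cc, d = dd, fold = fold, p = p)
}

signature_class_sets <- function(annotation, background,
                                 marks = c("DHS", "H3K4me1", "H3K4me3",
                                           "H3K27ac", "H3K27me3", "H3K9me3",
                                           "H3K36me3", "bivalent", "enhancer")) {
  ann <- annotation[annotation$IlmnID %in% background, ]
  region_classes <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
  sets <- list()
  groups <- strsplit(ann$UCSC_RefGene_Group, ";", fixed = TRUE)
  for (rc in region_classes) {
    inc <- vapply(groups, function(g) rc %in% g, logical(1))
    sets[[paste0("gene:", rc)]] <- ann$IlmnID[inc]
  }
  sets[["gene:Intergenic"]] <- ann$IlmnID[ann$UCSC_RefGene_Name == ""]
  for (ir in c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")) {
    sets[[paste0("island:", ir)]] <- ann$IlmnID[ann$Relation_to_UCSC_CpG_Island == ir]
  }
  for (m in intersect(marks, names(ann))) {
    sets[[paste0("chromatin:", m)]] <- ann$IlmnID[which(ann[[m]])]
  }
  sets
}

#' Enrichment of every signature, direction and annotation class
#'
#' Computes [fisher_enrichment()] rows for each signature split by hyper/hypo
#' direction across gene-region classes (including intergenic), CpG-island
#' relations, and chromatin marks with the derived bivalent and enhancer
#' classes. The Bonferroni family is all rows of one signature-direction
#' panel; rows are starred significant at adjusted p below `alpha`.
#'
#' @param signatures Named list of signature data frames, each with `probe`
#'   and `direction` columns (see [build_signatures()]).
#' @param annotation Probe annotation (with chromatin columns if mark
#'   enrichment is wanted).
#' @param background Character vector of all analyzed probe ids.
#' @param alpha Bonferroni-adjusted significance level, default 0.001.
#' @return Data frame with one row per signature x direction x class:
#'   signature, direction, class, counts, fold, p, `p_bonf` and `significant`.
#' @export
enrichment_matrix <- function(signatures, annotation, background,
                              alpha = 0.001) {
  sets <- signature_class_sets(annotation, background)
  rows <- list()
  for (nm in names(signatures)) {
    sig <- signatures[[nm]]
    panel <- list()
    for (dir in intersect(c("hyper", "hypo"), unique(sig$direction))) {
      ids <- intersect(sig$probe[sig$direction == dir], background)
      panel[[dir]] <- do.call(rbind, lapply(names(sets), function(cl) {
        r <- fisher_enrichment(ids, sets[[cl]], background)
        cbind(data.frame(signature = nm, direction = dir, class = cl,
                         stringsAsFactors = FALSE), r)
      }))
    }
    panel <- do.call(rbind, panel)
    if (is.null(panel)) next
    # Bonferroni family: all rows of one signature's panel (both directions)
    m <- sum(!is.na(panel$p))
    panel$p_bonf <- pmin(panel$p * m, 1)
    panel$significant <- !is.na(panel$p_bonf) & panel$p_bonf < alpha
    rows[[nm]] <- panel
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
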