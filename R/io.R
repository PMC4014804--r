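#' Read a probe-by-sample beta matrix from TSV
#'
#' First column holds probe ids, remaining columns one sample each. Values
#' must be fractions in `[0, 1]` (missing allowed); duplicate probe or sample
#' ids and non-numeric cells are errors.
#'
#' @param path TSV file path.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate probe id: ", ids[duplicated(ids)][1])
  }
  if (anyDuplicated(names(dt)[-1])) {
    stop("duplicate sample id: ", names(dt)[-1][duplicated(names(dt)[-1])][1])
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
    stop("non-numeric beta values in column '", names(dt)[-1][bad], "'")
  }
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1, ]
    stop("beta value outside [0,1] at probe '", ids[bad[1]], "', sample '",
         colnames(m)[bad[2]], "'")
  }
  rownames(m) <- ids
  m
}

#' Write a beta matrix to TSV
#'
#' Inverse of [read_beta()]; values are written with 6 decimals so a
#' write-read round trip is lossless at that precision.
#'
#' @param beta Probe-by-sample matrix.
#' @param path Output TSV path.
#' @export
write_beta <- function(beta, path) {
  dt <- data.table::data.table(probe = rownames(beta),
                               round(beta, 6))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Requires columns `sample_id`, `patient_id`, `role`, `cell_type`,
#' `subtype`, `phase`, `treatment`, `lineage`. Duplicate sample ids or
#' duplicate (patient, phase) combinations are errors.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_sheet <- function(path) {
  sheet <- data.table::fread(path, header = TRUE, data.table = FALSE,
                             na.strings = c("NA", ""))
  need <- c("sample_id", "patient_id", "role", "cell_type", "subtype",
            "phase", "treatment", "lineage")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample id: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1])
  }
  pp <- paste(sheet$patient_id, sheet$phase)
  if (anyDuplicated(pp)) {
    stop("duplicate (patient, phase): ", pp[duplicated(pp)][1])
  }
  sheet
}

#' Read a manifest-style probe annotation CSV
#'
#' Requires at least `IlmnID`, `CHR`, `MAPINFO`, `Infinium_Design_Type`,
#' `UCSC_RefGene_Name`, `UCSC_RefGene_Group`, `Relation_to_UCSC_CpG_Island`
#' and `SNP_flag`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  ann <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           na.strings = "NA")
  need <- c("IlmnID", "CHR", "MAPINFO", "Infinium_Design_Type",
            "UCSC_RefGene_Name", "UCSC_RefGene_Group",
            "Relation_to_UCSC_CpG_Island", "SNP_flag")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$IlmnID)) stop("duplicate probe id in annotation")
  ann$UCSC_RefGene_Name[is.na(ann$UCSC_RefGene_Name)] <- ""
  ann$UCSC_RefGene_Group[is.na(ann$UCSC_RefGene_Group)] <- ""
  ann
}

#' Read a genes-by-samples log2 expression TSV
#'
#' @param path TSV file path; first column gene symbols.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  g <- as.character(dt[[1]])
  if (anyDuplicated(g)) stop("duplicate gene id: ", g[duplicated(g)][1])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- g
  m
}

#' Write a simulated study to disk as plain-text files
#'
#' Emits the beta matrix (TSV), sample sheet (CSV), annotation (CSV),
#' expression matrix (TSV), outcomes (CSV), the truth set (JSON) and
#' per-mark, per-replicate peak BED files consistent with the annotation's
#' chromatin flags (each flagged probe is covered by a peak in at least two
#' of three replicates).
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created if absent).
#' @param n_replicates Replicate BED files per mark, default 3.
#' @return The output directory, invisibly.
#' @export
write_cohort <- function(sim, dir, n_replicates = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta(sim$beta, file.path(dir, "beta.tsv"))
  data.table::fwrite(sim$sheet, file.path(dir, "sample_sheet.csv"))
  data.table::fwrite(sim$annotation, file.path(dir, "annotation.csv"))
  if (!is.null(sim$expression)) {
    dt <- data.table::data.table(gene = rownames(sim$expression),
                                 round(sim$expression, 6))
    data.table::fwrite(dt, file.path(dir, "expression.tsv"), sep = "\t")
  }
  if (!is.null(sim$outcomes)) {
    data.table::fwrite(sim$outcomes, file.path(dir, "outcomes.csv"))
  }
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_peak_beds(sim$annotation, file.path(dir, "peaks"),
                  n_replicates = n_replicates,
                  seed = sim$truth$config$seed + 3L)
  invisible(dir)
}

#' Write replicate peak BED files consistent with chromatin flags
#'
#' For every chromatin mark column in the annotation, writes `n_replicates`
#' BED files (0-based half-open, 100 bp on either side of the probe). A
#' flagged probe receives a peak in at least `min_replicates` replicates; an
#' unflagged probe appears in at most one.
#'
#' @param annotation Probe annotation with logical mark columns.
#' @param dir Output directory.
#' @param marks Mark columns to write; default the seven primary marks
#'   present in the annotation.
#' @param n_replicates,min_replicates Replicate structure, defaults 3 and 2.
#' @param seed Integer seed for the replicate assignment.
#' @return Named list mark -> character vector of BED paths, invisibly.
#' @export
write_peak_beds <- function(annotation, dir,
                            marks = intersect(c("DHS", "H3K4me1", "H3K4me3",
                                                "H3K27ac", "H3K27me3",
                                                "H3K9me3", "H3K36me3"),
                                              names(annotation)),
                            n_replicates = 3L, min_replicates = 2L,
                            seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- list()
  for (m in marks) {
    flagged <- which(annotation[[m]])
    unflagged <- which(!annotation[[m]])
    # replicate membership: flagged in >= min_replicates, unflagged in <= 1
    reps <- matrix(FALSE, nrow = nrow(annotation), ncol = n_replicates)
    for (i in flagged) {
      k <- sample(min_replicates:n_replicates, 1L)
      reps[i, sample.int(n_replicates, k)] <- TRUE
    }
    lone <- unflagged[stats::runif(length(unflagged)) < 0.05]
    for (i in lone) reps[i, sample.int(n_replicates, 1L)] <- TRUE
    paths <- character(n_replicates)
    for (r in seq_len(n_replicates)) {
      idx <- which(reps[, r])
      bed <- data.frame(
        chrom = paste0("chr", annotation$CHR[idx]),
        start = pmax(annotation$MAPINFO[idx] - 101L, 0L),
        end = annotation$MAPINFO[idx] + 100L
      )
      path <- file.path(dir, sprintf("%s_rep%d.bed", gsub("/", "_", m), r))
      writeLines(c(sprintf("track name=%s_rep%d", m, r),
                   sprintf("%s\t%d\t%d", bed$chrom, bed$start, bed$end)),
                 path)
      paths[r] <- path
    }
    files[[m]] <- paths
  }
  invisible(files)
}

#' Analysis thresholds for the full pipeline
#'
#' Collects every numeric cut-off of the analysis in one validated object.
#' Defaults are the study's published values: minimum |delta beta| 0.2, DMC
#' FDR 0.01, reference SD 0.10, 10000 correlation permutations, 1000 survival
#' permutations, correlation alpha 0.05, fold change 2, 50-kb region window,
#' 2 CpGs per region, Bonferroni alpha 0.001.
#'
#' @param delta_beta,fdr,ref_sd,corr_perms,surv_perms,corr_alpha,fold_change
#'   Thresholds, see description.
#' @param region_window,min_region_cpgs,bonferroni_alpha More thresholds.
#' @param seed Integer seed for all stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(delta_beta = 0.2, fdr = 0.01, ref_sd = 0.10,
                            corr_perms = 10000, surv_perms = 1000,
                            corr_alpha = 0.05, fold_change = 2,
                            region_window = 50000, min_region_cpgs = 2,
                            bonferroni_alpha = 0.001, seed = 1L) {
  vals <- c(delta_beta, fdr, ref_sd, corr_perms, surv_perms, corr_alpha,
            fold_change, region_window, min_region_cpgs, bonferroni_alpha)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(delta_beta = delta_beta, fdr = fdr, ref_sd = ref_sd,
                 corr_perms = corr_perms, surv_perms = surv_perms,
                 corr_alpha = corr_alpha, fold_change = fold_change,
                 region_window = region_window,
                 min_region_cpgs = min_region_cpgs,
                 bonferroni_alpha = bonferroni_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a (simulated or loaded) study
#'
#' Normalizes type II probes by peak-based correction, filters probes to the
#' analysis universe, calls DMCs per subtype and for the relapse pairs,
#' assembles the constitutive / subtype-unique / relapse signatures, computes
#' functional enrichment, correlates signature CpGs with expression (when an
#' expression matrix is present), and summarizes the cohort by PCA. The
#' survival screen is run separately per stratum via [survival_screen()]
#' because its cost scales with permutations.
#'
#' @param study List with `beta`, `sheet`, `annotation` and optionally
#'   `expression` (as produced by [simulate_all()] or assembled from the
#'   readers).
#' @param config A [pipeline_config()].
#' @param correct Apply peak-based type II correction, default TRUE.
#' @param corr_B Correlation permutations actually used (defaults to
#'   `config$corr_perms`).
#' @return List with `beta` (corrected, filtered), `qc`, `dmc_tables`,
#'   `relapse_table`, `signatures`, `enrichment`, `correlation` (or NULL) and
#'   `pca`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), correct = TRUE,
                         corr_B = config$corr_perms) {
  beta <- study$beta
  qc <- NULL
  if (correct) {
    pc <- peak_correct(beta, study$annotation)
    beta <- pc$beta
    qc <- pc$qc
  }
  keep <- filter_probes(study$annotation)
  beta <- beta[intersect(rownames(beta), keep), , drop = FALSE]

  subtypes <- sort(unique(study$sheet$subtype[study$sheet$role == "ALL"]))
  tables <- lapply(subtypes, function(s) {
    call_dmcs(beta, study$sheet, s, delta_beta = config$delta_beta,
              fdr = config$fdr, ref_sd = config$ref_sd)
  })
  names(tables) <- subtypes
  relapse_table <- if (any(study$sheet$phase == "relapse1")) {
    call_relapse_dmcs(beta, study$sheet, delta_beta = config$delta_beta,
                      fdr = config$fdr, ref_sd = config$ref_sd)
  } else NULL

  signatures <- build_signatures(tables)
  sig_list <- list(constitutive = signatures$constitutive)
  for (s in subtypes) {
    u <- signatures$unique[signatures$unique$subtype == s, ]
    if (nrow(u)) sig_list[[paste0("unique:", s)]] <- u
  }
  if (!is.null(relapse_table)) {
    sig_list$relapse <- data.frame(
      probe = relapse_table$probe[relapse_table$is_dmc],
      direction = relapse_table$direction[relapse_table$is_dmc],
      stringsAsFactors = FALSE)
  }
  enrichment <- enrichment_matrix(sig_list, study$annotation,
                                  background = rownames(beta),
                                  alpha = config$bonferroni_alpha)

  correlation <- NULL
  if (!is.null(study$expression)) {
    # subtype-unique CpGs are contrasted within their own subtype
    per_sub <- lapply(subtypes, function(s) {
      u <- signatures$unique[signatures$unique$subtype == s, ]
      if (!nrow(u)) return(NULL)
      correlate_signature(u, beta, study$expression, study$annotation,
                          study$sheet, group_subtype = s, B = corr_B,
                          alpha = config$corr_alpha,
                          min_fold = config$fold_change, seed = config$seed)
    })
    correlation <- do.call(rbind, per_sub)
  }
  pca <- pca_summary(beta, n_components = min(10L, ncol(beta) - 1L))
  list(beta = beta, qc = qc, dmc_tables = tables,
       relapse_table = relapse_table, signatures = signatures,
       enrichment = enrichment, correlation = correlation, pca = pca)
}
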