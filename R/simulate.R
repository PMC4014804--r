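#' Configuration for the synthetic 450k-style ALL cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults describe
#' a desk-scale cohort mirroring the structure of the NOPHO pediatric ALL 450k
#' study (GEO GSE49031): ten cytogenetic/immunophenotypic subtypes with sample
#' counts scaled down roughly tenfold, a four-cell-type non-leukemic reference
#' panel, diagnosis-relapse pairs, a planted constitutive signature that is
#' almost entirely hypermethylated, per-subtype unique signatures, a
#' predominantly hypermethylated relapse signature, expression-coupled CpGs,
#' and prognostic regions whose methylation group multiplies the relapse
#' hazard.
#'
#' @param n_cpg Number of CpG probes.
#' @param n_per_subtype Named integer vector of diagnostic sample counts per
#'   subtype. `"T-ALL"` is T-lineage; all other subtypes are B-cell precursor.
#' @param n_reference Named integer vector of reference sample counts for cell
#'   types BM, CD19, CD3 and CD34.
#' @param n_relapse_pairs Number of patients with a paired first-relapse
#'   sample.
#' @param frac_constitutive,frac_subtype_unique,frac_relapse Fractions of
#'   probes planted as constitutive, per-subtype-unique (scalar or named per
#'   subtype) and relapse DMCs. Together they must not exceed 1.
#' @param constitutive_hyper_frac,subtype_hyper_frac,relapse_hyper_frac
#'   Probability that a planted DMC of each category is hypermethylated in the
#'   leukemic (or relapse) state. Defaults: 0.986 for the constitutive set,
#'   0.5 per subtype, 0.9 for relapse.
#' @param effect_delta Planted group-mean beta difference, default 0.5.
#' @param beta_precision Concentration `kappa` of the Beta noise
#'   `Beta(mu * kappa, (1 - mu) * kappa)` around the target mean, default 100.
#' @param typeII_fraction Fraction of probes assigned Infinium design type II.
#' @param typeII_compression M-value compression factor `c` in `(0, 1]`
#'   applied by [distort_type2()] to emulate the reduced dynamic range of type
#'   II probes; 1 means no distortion.
#' @param snp_frac,sex_frac Fractions of probes flagged for SNP interference
#'   or placed on chromosomes X/Y (both removed by [filter_probes()]).
#' @param n_corr_genes Number of genes whose expression is linearly coupled to
#'   a planted subtype-unique DMC.
#' @param n_noise_genes Number of additional uncoupled (pure noise) genes in
#'   the expression matrix.
#' @param expr_slope,expr_noise_sd,expr_intercept Parameters of the coupled
#'   expression model `log2 expr = intercept + sign * slope * beta + noise`.
#' @param prognostic_regions List of planted prognostic regions, each a list
#'   with `n_cpg` (CpGs in the region) and `hr`, a length-3 vector of relapse
#'   hazard ratios for the hypo / intermediate / hyper methylation groups.
#' @param prognostic_group_means Beta means of the three patient methylation
#'   groups at prognostic-region CpGs.
#' @param baseline_hazard,competing_rate,censoring_rate Per-year exponential
#'   rates for relapse (baseline), competing events, and random censoring.
#' @param followup_range Administrative follow-up window in years; each
#'   patient's maximum observation time is drawn uniformly from it.
#' @param chromatin_base Named per-mark Bernoulli base rates for the chromatin
#'   flags.
#' @param chromatin_boosts Data frame (`signature`, `mark`, `boost`) of
#'   log-odds boosts applied to the mark rates of planted signature CpGs;
#'   recorded in the truth set so enrichment recovery is checkable.
#' @param seed Integer seed fixing all generator output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(
    n_cpg = 10000,
    n_per_subtype = c("T-ALL" = 10, "HeH" = 19, "t(12;21)" = 16,
                      "11q23/MLL" = 5, "t(1;19)" = 5, "dic(9;20)" = 5,
                      "t(9;22)" = 5, "iAMP21" = 5, "undefined" = 11,
                      "non-recurrent" = 10),
    n_reference = c(BM = 9, CD19 = 6, CD3 = 6, CD34 = 5),
    n_relapse_pairs = 27,
    frac_constitutive = 0.02,
    frac_subtype_unique = 0.005,
    frac_relapse = 0.015,
    constitutive_hyper_frac = 0.986,
    subtype_hyper_frac = 0.5,
    relapse_hyper_frac = 0.9,
    effect_delta = 0.5,
    beta_precision = 100,
    typeII_fraction = 0.72,
    typeII_compression = 0.7,
    snp_frac = 0.02,
    sex_frac = 0.03,
    n_corr_genes = 40,
    n_noise_genes = 160,
    expr_slope = 4,
    expr_noise_sd = 0.35,
    expr_intercept = 6,
    prognostic_regions = list(list(n_cpg = 4, hr = c(5, 1, 1))),
    prognostic_group_means = c(0.15, 0.5, 0.85),
    baseline_hazard = 0.025,
    competing_rate = 0.01,
    censoring_rate = 0.02,
    followup_range = c(4.6, 18),
    chromatin_base = c(DHS = 0.12, H3K4me1 = 0.15, H3K4me3 = 0.10,
                       H3K27ac = 0.10, H3K27me3 = 0.15, H3K9me3 = 0.10,
                       H3K36me3 = 0.15),
    chromatin_boosts = data.frame(
      signature = c(rep("constitutive", 3), rep("subtype_unique", 3)),
      mark = c("H3K27me3", "H3K9me3", "H3K4me3", "DHS", "H3K4me1", "H3K4me3"),
      boost = c(1.1, 1.1, 0.7, 1.1, 1.1, 1.1),
      stringsAsFactors = FALSE
    ),
    seed = 1L) {
  subtypes <- names(n_per_subtype)
  if (is.null(subtypes)) stop("configuration error: n_per_subtype must be named")
  if (length(frac_subtype_unique) == 1L) {
    frac_subtype_unique <- stats::setNames(
      rep(frac_subtype_unique, length(subtypes)), subtypes)
  }
  if (length(subtype_hyper_frac) == 1L) {
    subtype_hyper_frac <- stats::setNames(
      rep(subtype_hyper_frac, length(subtypes)), subtypes)
  }
  fracs <- c(frac_constitutive, frac_subtype_unique, frac_relapse)
  if (any(fracs < 0 | fracs > 1)) {
    stop("configuration error: fractions must lie in [0, 1]")
  }
  if (frac_constitutive + sum(frac_subtype_unique) + frac_relapse > 1) {
    stop("configuration error: planted fractions sum to more than 1")
  }
  if (effect_delta <= 0 || effect_delta >= 1) {
    stop("configuration error: effect_delta must lie in (0, 1)")
  }
  if (beta_precision <= 0) stop("configuration error: beta_precision must be > 0")
  if (typeII_compression <= 0 || typeII_compression > 1) {
    stop("configuration error: typeII_compression must lie in (0, 1]")
  }
  cfg <- list(
    n_cpg = as.integer(n_cpg), n_per_subtype = n_per_subtype,
    n_reference = n_reference, n_relapse_pairs = as.integer(n_relapse_pairs),
    frac_constitutive = frac_constitutive,
    frac_subtype_unique = frac_subtype_unique, frac_relapse = frac_relapse,
    constitutive_hyper_frac = constitutive_hyper_frac,
    subtype_hyper_frac = subtype_hyper_frac,
    relapse_hyper_frac = relapse_hyper_frac,
    effect_delta = effect_delta, beta_precision = beta_precision,
    typeII_fraction = typeII_fraction, typeII_compression = typeII_compression,
    snp_frac = snp_frac, sex_frac = sex_frac,
    n_corr_genes = as.integer(n_corr_genes),
    n_noise_genes = as.integer(n_noise_genes),
    expr_slope = expr_slope, expr_noise_sd = expr_noise_sd,
    expr_intercept = expr_intercept,
    prognostic_regions = prognostic_regions,
    prognostic_group_means = prognostic_group_means,
    baseline_hazard = baseline_hazard, competing_rate = competing_rate,
    censoring_rate = censoring_rate, followup_range = followup_range,
    chromatin_base = chromatin_base, chromatin_boosts = chromatin_boosts,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

clamp_mu <- function(mu) pmin(pmax(mu, 0.02), 0.98)

# Background mean mixture: low / intermediate / high components emulating the
# bimodal 450k beta distribution.
draw_background_means <- function(n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.20, 0.45))
  mu <- numeric(n)
  mu[comp == 1] <- stats::runif(sum(comp == 1), 0.05, 0.15)
  mu[comp == 2] <- stats::runif(sum(comp == 2), 0.30, 0.70)
  mu[comp == 3] <- stats::runif(sum(comp == 3), 0.85, 0.95)
  mu
}

#' Generate a synthetic 450k-style ALL cohort with a truth set
#'
#' Draws a probe-by-sample beta matrix, sample sheet and manifest-style probe
#' annotation under the statistical structure the downstream analysis assumes:
#' bimodal background methylation shared by all non-leukemic reference cell
#' types, planted constitutive / subtype-unique / relapse DMCs that shift the
#' group mean by `effect_delta` (means clamped to `[0.02, 0.98]` before Beta
#' sampling), prognostic regions with three patient methylation groups, and
#' chromatin flags whose rates are boosted for designated signature sets. All
#' planted structure is returned in a machine-readable truth set.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `beta` (probes x samples matrix), `sheet`
#'   (sample sheet data frame), `annotation` (probe annotation data frame) and
#'   `truth` (list of planted ids, directions, coupled genes, prognostic
#'   assignments and chromatin boosts).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cpg
  probes <- sprintf("cg%07d", seq_len(n))

  ## --- genomic annotation -------------------------------------------------
  n_sex <- round(config$sex_frac * n)
  chr <- character(n)
  sex_idx <- if (n_sex > 0) sample.int(n, n_sex) else integer(0)
  chr[sex_idx] <- sample(c("X", "Y"), n_sex, replace = TRUE, prob = c(0.8, 0.2))
  auto_idx <- setdiff(seq_len(n), sex_idx)
  chr[auto_idx] <- sample(as.character(1:22), length(auto_idx), replace = TRUE)

  pos <- integer(n)
  gene_name <- character(n)
  gene_group <- character(n)
  gene_counter <- 0L
  region_classes <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
  region_probs <- c(0.15, 0.12, 0.10, 0.08, 0.45, 0.10)
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    idx <- idx[order(idx)]
    pos[idx] <- cumsum(round(stats::runif(length(idx), 500, 5000))) + 10000L
    i <- 1L
    while (i <= length(idx)) {
      if (stats::runif(1) < 0.7) {
        gene_counter <- gene_counter + 1L
        gname <- sprintf("gene%05d", gene_counter)
        len <- min(sample.int(8L, 1L) , length(idx) - i + 1L)
        block <- idx[i:(i + len - 1L)]
        gene_name[block] <- gname
        gene_group[block] <- sample(region_classes, len, replace = TRUE,
                                    prob = region_probs)
        i <- i + len
      } else {
        len <- min(sample.int(4L, 1L), length(idx) - i + 1L)
        i <- i + len
      }
    }
  }
  # occasional second annotation for the same gene (e.g. TSS200 and 1stExon)
  two <- which(gene_name != "" & stats::runif(n) < 0.05)
  for (i in two) {
    extra <- sample(setdiff(region_classes, gene_group[i]), 1L)
    gene_name[i] <- paste(gene_name[i], sub(";.*", "", gene_name[i]), sep = ";")
    gene_group[i] <- paste(gene_group[i], extra, sep = ";")
  }

  island <- sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                     "OpenSea"), n, replace = TRUE,
                   prob = c(0.31, 0.12, 0.11, 0.05, 0.05, 0.36))
  design <- ifelse(stats::runif(n) < config$typeII_fraction, "II", "I")
  snp <- stats::runif(n) < config$snp_frac

  ## --- planted probe sets -------------------------------------------------
  eligible <- which(!(chr %in% c("X", "Y")) & !snp)
  eligible <- sample(eligible)  # shuffled pool; slices are disjoint
  take <- function(k) {
    if (k > length(eligible)) stop("not enough eligible probes to plant signals")
    out <- eligible[seq_len(k)]
    eligible <<- eligible[-seq_len(k)]
    out
  }
  subtypes <- names(config$n_per_subtype)
  n_const <- round(config$frac_constitutive * n)
  const_idx <- take(n_const)
  uniq_idx <- lapply(subtypes, function(s) {
    take(round(config$frac_subtype_unique[[s]] * n))
  })
  names(uniq_idx) <- subtypes
  relapse_idx <- take(round(config$frac_relapse * n))

  # prognostic regions: runs of consecutive probes inside one gene
  prog_regions <- list()
  used <- c(const_idx, unlist(uniq_idx), relapse_idx)
  for (r in seq_along(config$prognostic_regions)) {
    want <- config$prognostic_regions[[r]]$n_cpg
    base_gene <- sub(";.*", "", gene_name)
    cand_genes <- names(which(table(base_gene[base_gene != "" &
                                                !(seq_len(n) %in% used) &
                                                !(chr %in% c("X", "Y")) &
                                                !snp]) >= want))
    if (!length(cand_genes)) stop("no gene large enough for a prognostic region")
    g <- sample(cand_genes, 1L)
    gidx <- which(base_gene == g & !(seq_len(n) %in% used))[seq_len(want)]
    used <- c(used, gidx)
    prog_regions[[r]] <- list(gene = g, idx = gidx,
                              hr = config$prognostic_regions[[r]]$hr)
  }

  dir_draw <- function(k, p_hyper) {
    ifelse(stats::runif(k) < p_hyper, 1, -1)
  }
  const_dir <- dir_draw(n_const, config$constitutive_hyper_frac)
  uniq_dir <- lapply(subtypes, function(s) {
    dir_draw(length(uniq_idx[[s]]), config$subtype_hyper_frac[[s]])
  })
  names(uniq_dir) <- subtypes
  relapse_dir <- dir_draw(length(relapse_idx), config$relapse_hyper_frac)

  ## --- background means (planted sites get headroom for the full shift) ---
  mu0 <- draw_background_means(n)
  d <- config$effect_delta
  plant_mu <- function(idx, dir) {
    hi <- dir > 0
    mu0[idx[hi]] <<- stats::runif(sum(hi), 0.05, min(0.45, 0.98 - d))
    mu0[idx[!hi]] <<- stats::runif(sum(!hi), max(0.55, 0.02 + d), 0.95)
  }
  plant_mu(const_idx, const_dir)
  for (s in subtypes) plant_mu(uniq_idx[[s]], uniq_dir[[s]])
  plant_mu(relapse_idx, relapse_dir)

  ## --- sample sheet -------------------------------------------------------
  ref_rows <- do.call(rbind, lapply(names(config$n_reference), function(ct) {
    k <- config$n_reference[[ct]]
    if (k == 0) return(NULL)
    data.frame(sample_id = sprintf("ref_%s_%02d", ct, seq_len(k)),
               patient_id = sprintf("ref_%s_%02d", ct, seq_len(k)),
               role = "reference", cell_type = ct, subtype = NA_character_,
               phase = "reference", treatment = NA_character_,
               lineage = NA_character_, stringsAsFactors = FALSE)
  }))
  all_rows <- do.call(rbind, lapply(subtypes, function(s) {
    k <- config$n_per_subtype[[s]]
    data.frame(subtype = s, lineage = if (s == "T-ALL") "T" else "B",
               n = seq_len(k), stringsAsFactors = FALSE)
  }))
  n_all <- nrow(all_rows)
  all_sheet <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_all)),
    patient_id = sprintf("P%04d", seq_len(n_all)),
    role = "ALL", cell_type = NA_character_,
    subtype = all_rows$subtype, phase = "diagnosis",
    treatment = sample(c("SR", "IR", "HR"), n_all, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    lineage = all_rows$lineage, stringsAsFactors = FALSE
  )
  n_pairs <- min(config$n_relapse_pairs, n_all)
  pair_rows <- if (n_pairs > 0) sort(sample.int(n_all, n_pairs)) else integer(0)
  relapse_sheet <- if (n_pairs > 0) {
    data.frame(
      sample_id = paste0(all_sheet$sample_id[pair_rows], "_r1"),
      patient_id = all_sheet$patient_id[pair_rows],
      role = "ALL", cell_type = NA_character_,
      subtype = all_sheet$subtype[pair_rows], phase = "relapse1",
      treatment = all_sheet$treatment[pair_rows],
      lineage = all_sheet$lineage[pair_rows], stringsAsFactors = FALSE
    )
  } else NULL
  sheet <- rbind(ref_rows, all_sheet, relapse_sheet)
  rownames(sheet) <- NULL

  ## --- mean matrix and beta draws ----------------------------------------
  n_samp <- nrow(sheet)
  mu <- matrix(mu0, nrow = n, ncol = n_samp)
  colnames(mu) <- sheet$sample_id
  leuk <- sheet$role == "ALL"
  for (j in which(leuk)) {
    s <- sheet$subtype[j]
    mu[const_idx, j] <- mu[const_idx, j] + d * const_dir
    if (length(uniq_idx[[s]])) {
      mu[uniq_idx[[s]], j] <- mu[uniq_idx[[s]], j] + d * uniq_dir[[s]]
    }
    if (sheet$phase[j] == "relapse1" && length(relapse_idx)) {
      mu[relapse_idx, j] <- mu[relapse_idx, j] + d * relapse_dir
    }
  }
  # prognostic regions: patient methylation group overrides the background
  prog_groups <- NULL
  if (length(prog_regions)) {
    pts <- unique(sheet$patient_id[leuk])
    grp <- sample.int(3L, length(pts), replace = TRUE)
    prog_groups <- data.frame(patient_id = pts,
                              group = c("hypo", "intermediate", "hyper")[grp],
                              stringsAsFactors = FALSE)
    gm <- config$prognostic_group_means
    for (rg in prog_regions) {
      for (j in which(leuk)) {
        g <- grp[match(sheet$patient_id[j], pts)]
        mu[rg$idx, j] <- gm[g]
      }
      mu[rg$idx, !leuk] <- gm[2]
    }
  }
  mu <- clamp_mu(mu)
  kappa <- config$beta_precision
  beta <- matrix(stats::rbeta(length(mu), mu * kappa, (1 - mu) * kappa),
                 nrow = n, ncol = n_samp,
                 dimnames = list(probes, sheet$sample_id))

  ## --- chromatin flags ----------------------------------------------------
  marks <- names(config$chromatin_base)
  logit <- function(p) log(p / (1 - p))
  chrom <- matrix(FALSE, nrow = n, ncol = length(marks),
                  dimnames = list(NULL, marks))
  uniq_all <- unlist(uniq_idx)
  for (m in marks) {
    eta <- rep(logit(config$chromatin_base[[m]]), n)
    bst <- config$chromatin_boosts
    b_const <- bst$boost[bst$signature == "constitutive" & bst$mark == m]
    b_uniq <- bst$boost[bst$signature == "subtype_unique" & bst$mark == m]
    if (length(b_const)) eta[const_idx] <- eta[const_idx] + b_const
    if (length(b_uniq)) eta[uniq_all] <- eta[uniq_all] + b_uniq
    chrom[, m] <- stats::runif(n) < stats::plogis(eta)
  }

  annotation <- data.frame(
    IlmnID = probes, CHR = chr, MAPINFO = pos,
    Infinium_Design_Type = design,
    UCSC_RefGene_Name = gene_name, UCSC_RefGene_Group = gene_group,
    Relation_to_UCSC_CpG_Island = island, SNP_flag = snp,
    stringsAsFactors = FALSE
  )
  annotation <- cbind(annotation, as.data.frame(chrom))
  annotation$bivalent <- annotation$H3K4me3 & annotation$H3K27me3
  annotation$enhancer <- annotation$H3K4me1 & annotation$H3K27ac

  ## --- expression coupling targets ----------------------------------------
  anchors <- unlist(uniq_idx)
  anchors <- anchors[gene_name[anchors] != ""]
  anchors <- anchors[!duplicated(sub(";.*", "", gene_name[anchors]))]
  n_corr <- min(config$n_corr_genes, length(anchors))
  anchors <- if (n_corr > 0) sample(anchors, n_corr) else integer(0)
  corr_genes <- data.frame(
    gene = sub(";.*", "", gene_name[anchors]),
    probe = probes[anchors],
    sign = ifelse(stats::runif(n_corr) < 0.7, -1, 1),
    stringsAsFactors = FALSE
  )

  truth <- list(
    constitutive = data.frame(probe = probes[const_idx],
                              direction = ifelse(const_dir > 0, "hyper", "hypo"),
                              stringsAsFactors = FALSE),
    subtype_unique = do.call(rbind, lapply(subtypes, function(s) {
      if (!length(uniq_idx[[s]])) return(NULL)
      data.frame(probe = probes[uniq_idx[[s]]], subtype = s,
                 direction = ifelse(uniq_dir[[s]] > 0, "hyper", "hypo"),
                 stringsAsFactors = FALSE)
    })),
    relapse = data.frame(probe = probes[relapse_idx],
                         direction = ifelse(relapse_dir > 0, "hyper", "hypo"),
                         stringsAsFactors = FALSE),
    correlated_genes = corr_genes,
    prognostic = list(
      regions = lapply(prog_regions, function(rg) {
        list(gene = rg$gene, probes = probes[rg$idx], hr = rg$hr)
      }),
      groups = prog_groups,
      group_means = config$prognostic_group_means
    ),
    chromatin_boosts = cbind(
      config$chromatin_boosts,
      base_rate = config$chromatin_base[config$chromatin_boosts$mark]
    ),
    config = config
  )
  list(beta = beta, sheet = sheet, annotation = annotation, truth = truth)
}

#' Compress the dynamic range of type II probes
#'
#' Emulates the reduced dynamic range of Infinium type II chemistry by scaling
#' M-values of type II probes: `beta <- logistic2(c * logit2(beta))`. Type I
#' probes are untouched. This is the distortion that [peak_correct()] is
#' designed to remove.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param annotation Probe annotation with `IlmnID` and
#'   `Infinium_Design_Type`.
#' @param c Compression factor in `(0, 1]`; 1 is the identity.
#' @return Distorted beta matrix.
#' @export
distort_type2 <- function(beta, annotation, c) {
  stopifnot(c > 0, c <= 1)
  design <- annotation$Infinium_Design_Type[match(rownames(beta),
                                                 annotation$IlmnID)]
  is2 <- design == "II"
  out <- beta
  out[is2, ] <- m_to_beta(c * beta_to_m(beta[is2, , drop = FALSE]))
  out
}

#' Generate expression data coupled to planted DMCs
#'
#' For each coupled gene in the truth set, log2 expression is
#' `intercept + sign * slope * beta(anchor CpG) + Gaussian noise`, producing
#' strong planted methylation-expression correlations and at least two-fold
#' group differences at the default slope. Uncoupled genes are pure noise.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The same [sim_config()] used to build the cohort.
#' @return Genes-by-samples matrix of log2 expression for all diagnostic ALL
#'   and reference samples.
#' @export
simulate_expression <- function(cohort, config = cohort$truth$config) {
  set.seed(config$seed + 1L)
  sheet <- cohort$sheet
  keep <- sheet$phase %in% c("diagnosis", "reference")
  ids <- sheet$sample_id[keep]
  corr <- cohort$truth$correlated_genes
  base_gene <- sub(";.*", "", cohort$annotation$UCSC_RefGene_Name)
  # uncoupled genes: preferentially those annotated to planted signature CpGs
  # (so the expression matrix covers the signatures, as real arrays would),
  # topped up with random other genes
  sig_probes <- unique(c(cohort$truth$subtype_unique$probe,
                         cohort$truth$constitutive$probe))
  sig_genes <- unique(base_gene[match(sig_probes, cohort$annotation$IlmnID)])
  sig_genes <- setdiff(sig_genes[!is.na(sig_genes) & sig_genes != ""], corr$gene)
  other <- setdiff(unique(base_gene[base_gene != ""]),
                   c(corr$gene, sig_genes))
  pool <- c(sample(sig_genes), sample(other))
  noise_genes <- utils::head(pool, min(config$n_noise_genes, length(pool)))
  genes <- c(corr$gene, noise_genes)
  expr <- matrix(stats::rnorm(length(genes) * length(ids),
                              mean = config$expr_intercept,
                              sd = config$expr_noise_sd),
                 nrow = length(genes), ncol = length(ids),
                 dimnames = list(genes, ids))
  if (nrow(corr)) {
    b <- cohort$beta[corr$probe, ids, drop = FALSE]
    expr[seq_len(nrow(corr)), ] <- expr[seq_len(nrow(corr)), ] +
      corr$sign * config$expr_slope * b
  }
  expr
}

#' Generate relapse-free-survival outcomes coupled to prognostic regions
#'
#' Each diagnostic patient receives a latent relapse time drawn from an
#' exponential whose rate is the baseline hazard multiplied by the hazard
#' ratio of the patient's methylation group at every planted prognostic
#' region, an independent competing-event time, and an independent censoring
#' time (exponential, truncated by an administrative follow-up window). The
#' observed record is the earliest of the three.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The same [sim_config()] used to build the cohort.
#' @return Data frame with `patient_id`, `time` (years), `event`
#'   (`"relapse"`, `"other_event"`, `"censored"`), `subtype`, `treatment` and
#'   `stratum`.
#' @export
simulate_outcomes <- function(cohort, config = cohort$truth$config) {
  set.seed(config$seed + 2L)
  sheet <- cohort$sheet
  dg <- sheet[sheet$role == "ALL" & sheet$phase == "diagnosis", ]
  npt <- nrow(dg)
  rate <- rep(config$baseline_hazard, npt)
  groups <- cohort$truth$prognostic$groups
  if (!is.null(groups)) {
    glab <- groups$group[match(dg$patient_id, groups$patient_id)]
    gi <- match(glab, c("hypo", "intermediate", "hyper"))
    for (rg in cohort$truth$prognostic$regions) {
      rate <- rate * rg$hr[gi]
    }
  }
  t_rel <- stats::rexp(npt, rate)
  t_cmp <- stats::rexp(npt, config$competing_rate)
  t_cns <- pmin(stats::rexp(npt, config$censoring_rate),
                stats::runif(npt, config$followup_range[1],
                             config$followup_range[2]))
  time <- pmin(t_rel, t_cmp, t_cns)
  event <- ifelse(time == t_rel, "relapse",
                  ifelse(time == t_cmp, "other_event", "censored"))
  data.frame(
    patient_id = dg$patient_id,
    time = time,
    event = event,
    subtype = dg$subtype,
    treatment = dg$treatment,
    stratum = paste(dg$subtype, dg$treatment, sep = ":"),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic study (methylation, expression, outcomes)
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_expression()]
#' and [simulate_outcomes()] from one configuration.
#'
#' @param config A [sim_config()] object.
#' @return List with `beta`, `sheet`, `annotation`, `truth`, `expression` and
#'   `outcomes`.
#' @export
simulate_all <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  cohort$expression <- simulate_expression(cohort, config)
  cohort$outcomes <- simulate_outcomes(cohort, config)
  cohort
}
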