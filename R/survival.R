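#' Train a nearest shrunken centroids classifier
#'
#' Standardized class-centroid differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)` are soft-thresholded by `delta`,
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`, and the shrunken centroids
#' are reconstructed as `xbar_i + m_k * (s_i + s0) * d'_ik`. `s_i` is the
#' pooled within-class standard deviation and the fudge `s0` is the median of
#' the `s_i`.
#'
#' @param X Samples-by-features numeric matrix.
#' @param y Class labels (factor or character), one per row of `X`; every
#'   class needs at least 2 samples.
#' @param delta Non-negative shrinkage threshold; 0 recovers the diagonal
#'   nearest-centroid rule.
#' @param priors Class prior probabilities; default the class frequencies.
#' @return Object of class `nsc_model`.
#' @export
nsc_train <- function(X, y, delta = 0, priors = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  n_k <- table(factor(y, levels = classes))
  if (any(n_k < 2)) {
    stop("every class needs at least 2 samples; got: ",
         paste(sprintf("%s=%d", names(n_k), n_k), collapse = ", "))
  }
  n <- nrow(X)
  K <- length(classes)
  overall <- colMeans(X)
  centroids <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                        numeric(ncol(X))))
  # pooled within-class variance
  ss <- Reduce(`+`, lapply(classes, function(k) {
    xk <- X[y == k, , drop = FALSE]
    colSums(sweep(xk, 2L, colMeans(xk))^2)
  }))
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  m_k <- sqrt(1 / as.numeric(n_k) - 1 / n)
  d <- sweep(centroids, 2L, overall) /
    (m_k %o% (s + s0))
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken <- sweep(m_k %o% (s + s0) * d_shrunk, 2L, overall, `+`)
  if (is.null(priors)) priors <- as.numeric(n_k) / n
  structure(list(
    classes = classes, features = colnames(X),
    overall = overall, centroids = centroids,
    s = s, s0 = s0, m_k = m_k, n_k = as.numeric(n_k),
    priors = priors, delta = delta,
    d = d, d_shrunk = d_shrunk, shrunken_centroids = shrunken
  ), class = "nsc_model")
}

# re-threshold a fitted model at a new delta (the unshrunk d is delta-free)
nsc_shrink <- function(model, delta) {
  model$delta <- delta
  model$d_shrunk <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  model$shrunken_centroids <- sweep(
    model$m_k %o% (model$s + model$s0) * model$d_shrunk,
    2L, model$overall, `+`)
  model
}

#' Predict classes and class scores from an NSC model
#'
#' The discriminant is
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`; the
#' predicted class minimizes it (ties broken by class order, with a message)
#' and the per-class scores are softmax-style probabilities
#' `exp(-delta_k / 2)` normalized over classes.
#'
#' @param model An `nsc_model` from [nsc_train()].
#' @param newx Matrix of samples by features (or a single numeric vector).
#' @return List with `class` (character vector) and `posterior` (matrix of
#'   class scores, columns in `model$classes` order).
#' @export
nsc_predict <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  newx <- as.matrix(newx)
  denom <- (model$s + model$s0)^2
  disc <- vapply(seq_along(model$classes), function(k) {
    rowSums(sweep(newx, 2L, model$shrunken_centroids[k, ])^2 /
              rep(denom, each = nrow(newx))) - 2 * log(model$priors[k])
  }, numeric(nrow(newx)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  colnames(disc) <- model$classes
  ties <- apply(disc, 1L, function(r) sum(r == min(r)) > 1L)
  cls <- model$classes[apply(disc, 1L, which.min)]  # ties: first class kept
  ex <- exp(-(disc - apply(disc, 1L, min)) / 2)
  posterior <- ex / rowSums(ex)
  list(class = cls, posterior = posterior, n_ties = sum(ties))
}

#' Area under the ROC curve by the Mann-Whitney formulation
#'
#' Probability that a positive-class score outranks a negative-class score,
#' with ties counted one half.
#'
#' @param scores Numeric score vector.
#' @param labels Class labels aligned with `scores`.
#' @param positive Label of the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# |d'| of the positive class for a binary NSC fit on X[tr, ]: the same
# quantities nsc_train produces, computed with two colMeans and a
# precomputed column sum of squares (hot path of score_cpgs permutations)
nsc_dpos_shrunk <- function(X, tr, pos, delta, colsq) {
  n <- length(tr)
  np <- sum(pos); nn <- n - np
  mu_p <- colMeans(X[tr[pos], , drop = FALSE])
  mu_n <- colMeans(X[tr[!pos], , drop = FALSE])
  overall <- (np * mu_p + nn * mu_n) / n
  ss <- colsq - np * mu_p^2 - nn * mu_n^2
  s <- sqrt(pmax(ss, 0) / (n - 2))
  s0 <- stats::median(s)
  m_pos <- sqrt(1 / np - 1 / n)
  d <- (mu_p - overall) / (m_pos * (s + s0))
  pmax(abs(d) - delta, 0)
}

# stratified fold assignment: class-balanced round-robin after shuffling
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated AUC of an NSC relapse classifier
#'
#' Runs `repeats` rounds of stratified `folds`-fold cross-validation. Inside
#' every training split the shrinkage `delta` is chosen from a grid by nested
#' cross-validation (maximizing inner pooled AUC); out-of-fold scores for the
#' positive class are pooled within each repeat into one AUC, and the mean
#' over repeats is reported.
#'
#' @param X Samples-by-features matrix.
#' @param y Class labels; the positive class is `positive`.
#' @param positive Positive-class label, default `"relapse"`.
#' @param folds Number of CV folds, default 5.
#' @param repeats Number of CV repetitions, default 100.
#' @param n_delta Size of the shrinkage grid (0 to max |d|), default 30.
#' @param nested_folds Folds of the inner delta-selection CV, default 5.
#' @param seed Integer seed.
#' @return List with `auc` (mean over repeats), `auc_per_repeat`,
#'   `oof_scores` (per-sample out-of-fold positive-class score, averaged over
#'   repeats) and `chosen_deltas`.
#' @export
repeated_cv_auc <- function(X, y, positive = "relapse", folds = 5,
                            repeats = 100, n_delta = 30, nested_folds = 5,
                            seed = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  stopifnot(length(unique(y)) == 2, positive %in% y)
  set.seed(seed)
  n <- nrow(X)
  auc_rep <- numeric(repeats)
  score_sum <- numeric(n)
  score_cnt <- numeric(n)
  deltas <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- make_folds(y, folds)
    oof <- rep(NA_real_, n)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 2) next
      delta_star <- choose_delta(X[tr, , drop = FALSE], y[tr], positive,
                                 nested_folds, n_delta)
      fit <- nsc_train(X[tr, , drop = FALSE], y[tr], delta = delta_star)
      pr <- nsc_predict(fit, X[!tr, , drop = FALSE])
      oof[!tr] <- pr$posterior[, positive]
      deltas <- c(deltas, delta_star)
    }
    ok <- !is.na(oof)
    auc_rep[r] <- auc_score(oof[ok], y[ok], positive)
    score_sum[ok] <- score_sum[ok] + oof[ok]
    score_cnt[ok] <- score_cnt[ok] + 1
  }
  list(auc = mean(auc_rep), auc_per_repeat = auc_rep,
       oof_scores = ifelse(score_cnt > 0, score_sum / score_cnt, NA_real_),
       chosen_deltas = deltas)
}

# linear relapse-vs-rest score of a two-class NSC fit for a whole delta grid:
# for K = 2 the discriminant difference is linear in x, so every delta is one
# column of a single matrix product. Higher score = more positive-class-like.
nsc_grid_scores <- function(fit, X, grid, positive) {
  kp <- match(positive, fit$classes)
  ko <- if (kp == 1L) 2L else 1L
  denom <- (fit$s + fit$s0)^2
  W <- vapply(grid, function(dl) {
    dsh <- sign(fit$d) * pmax(abs(fit$d) - dl, 0)
    cent <- sweep(fit$m_k %o% (fit$s + fit$s0) * dsh, 2L, fit$overall, `+`)
    2 * (cent[kp, ] - cent[ko, ]) / denom
  }, numeric(ncol(X)))
  X %*% W  # constant offsets do not affect ranking
}

# inner-CV selection of the shrinkage threshold (two-class fast path)
choose_delta <- function(X, y, positive, folds, n_delta) {
  base <- nsc_train(X, y, delta = 0)
  grid <- seq(0, max(abs(base$d)), length.out = n_delta)
  fold <- make_folds(y, folds)
  oof <- matrix(NA_real_, nrow = nrow(X), ncol = n_delta)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 2) next
    fit <- nsc_train(X[tr, , drop = FALSE], y[tr], delta = 0)
    oof[!tr, ] <- nsc_grid_scores(fit, X[!tr, , drop = FALSE], grid, positive)
  }
  aucs <- vapply(seq_len(n_delta), function(g) {
    ok <- !is.na(oof[, g])
    if (!any(ok) || length(unique(y[ok])) < 2) return(NA_real_)
    auc_score(oof[ok, g], y[ok], positive)
  }, numeric(1))
  if (all(is.na(aucs))) return(0)
  grid[which.max(aucs)]  # first max: smallest delta among ties
}

#' Permutation test of a signature's cross-validated AUC
#'
#' Re-runs the repeated-CV AUC on `B` datasets with class labels permuted
#' (within strata when supplied) and reports
#' `p = (1 + #(AUC_perm >= AUC_obs)) / (B + 1)`.
#'
#' @inheritParams repeated_cv_auc
#' @param strata Optional stratum labels; permutations shuffle labels only
#'   within a stratum.
#' @param B Number of permutations, default 1000.
#' @param repeats CV repeats used for the observed and each permuted AUC.
#' @return List with `auc`, `p` and the permutation AUC vector.
#' @export
permutation_test_signature <- function(X, y, strata = NULL, B = 1000,
                                       positive = "relapse", folds = 5,
                                       repeats = 5, n_delta = 15,
                                       nested_folds = 3, seed = 1L) {
  y <- as.character(y)
  obs <- repeated_cv_auc(X, y, positive, folds, repeats, n_delta,
                         nested_folds, seed)$auc
  if (is.null(strata)) strata <- rep(1L, length(y))
  set.seed(seed + 1L)
  perm_auc <- vapply(seq_len(B), function(b) {
    yp <- y
    for (s in unique(strata)) {
      idx <- which(strata == s)
      yp[idx] <- y[sample(idx)]
    }
    if (length(unique(yp)) < 2 || min(table(yp)) < 2) return(NA_real_)
    repeated_cv_auc(X, yp, positive, folds, repeats, n_delta, nested_folds,
                    seed = seed + 1L + b)$auc
  }, numeric(1))
  perm_auc <- perm_auc[!is.na(perm_auc)]
  list(auc = obs,
       p = (1 + sum(perm_auc >= obs)) / (length(perm_auc) + 1),
       perm_auc = perm_auc)
}

#' Score CpGs by their shrunken NSC coefficients with permutation p-values
#'
#' Each CpG is scored by the absolute shrunken coefficient `|d'_ik|` for the
#' positive class of an NSC fit on the full training data, with the shrinkage
#' `delta` chosen by cross-validation (the median over `repeats` repeated
#' fold draws of the CV-optimal delta). Significance is the tail probability
#' of that score under label permutation, conditioning on the chosen delta:
#' permutations randomize labels only, so the reference distribution measures
#' label association rather than grid-selection variability.
#'
#' @inheritParams repeated_cv_auc
#' @param B Number of label permutations for the per-CpG reference
#'   distribution, default 100.
#' @param repeats Repeated fold draws used to stabilize the delta choice,
#'   default 5.
#' @return Data frame with `probe`, `score`, permutation `p`, and the chosen
#'   `delta` as an attribute.
#' @export
score_cpgs <- function(X, y, positive = "relapse", folds = 5, repeats = 5,
                       B = 100, n_delta = 15, nested_folds = 3, seed = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  stopifnot(length(unique(y)) == 2, positive %in% y)
  set.seed(seed)

  # delta by repeated cross-validation on the training data
  deltas <- vapply(seq_len(repeats), function(r) {
    choose_delta(X, y, positive, folds, n_delta)
  }, numeric(1))
  delta_star <- stats::median(deltas)

  all_rows <- seq_len(nrow(X))
  colsq <- colSums(X^2)
  obs <- nsc_dpos_shrunk(X, all_rows, y == positive, delta_star, colsq)

  # conditional permutation reference: labels are randomized, the chosen
  # shrinkage is replayed
  exceed <- numeric(ncol(X))
  for (b in seq_len(B)) {
    yp <- sample(y)
    sc <- nsc_dpos_shrunk(X, all_rows, yp == positive, delta_star, colsq)
    exceed <- exceed + (sc >= obs)
  }
  out <- data.frame(probe = colnames(X), score = obs,
                    p = (1 + exceed) / (B + 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "delta") <- delta_star
  out
}

#' Aggregate significant CpGs into candidate genomic regions
#'
#' A candidate region is (a) a gene carrying at least `min_cpgs` significant
#' CpGs, or (b) a maximal chain of at least `min_cpgs` significant CpGs in
#' which consecutive sites lie within `window` bases of each other. Regions
#' with identical CpG membership are merged.
#'
#' @param sig_probes Character vector of significant CpG ids.
#' @param annotation Probe annotation with `IlmnID`, `CHR`, `MAPINFO` and
#'   `UCSC_RefGene_Name`.
#' @param window Chain window in bases, default 50000 (50 kb).
#' @param min_cpgs Minimum CpGs per region, default 2.
#' @return Data frame with `region`, `type` (`"gene"`/`"chain"`), `chr`, and
#'   a `probes` list-column of member CpGs.
#' @export
aggregate_regions <- function(sig_probes, annotation, window = 50000,
                              min_cpgs = 2L) {
  ann <- annotation[match(sig_probes, annotation$IlmnID), ]
  regions <- list()
  # gene rule (every annotated gene of a multi-gene probe counts)
  genes <- strsplit(ann$UCSC_RefGene_Name, ";", fixed = TRUE)
  pairs <- do.call(rbind, lapply(seq_along(sig_probes), function(i) {
    g <- unique(genes[[i]]); g <- g[!is.na(g) & g != ""]
    if (!length(g)) return(NULL)
    data.frame(probe = sig_probes[i], gene = g, stringsAsFactors = FALSE)
  }))
  if (!is.null(pairs)) {
    for (g in unique(pairs$gene)) {
      members <- pairs$probe[pairs$gene == g]
      if (length(members) >= min_cpgs) {
        regions[[length(regions) + 1L]] <- list(
          region = g, type = "gene",
          chr = ann$CHR[match(members[1], sig_probes)],
          probes = sort(members))
      }
    }
  }
  # 50-kb chain rule
  for (cc in unique(ann$CHR)) {
    idx <- which(ann$CHR == cc)
    idx <- idx[order(ann$MAPINFO[idx])]
    if (length(idx) < min_cpgs) next
    gaps <- diff(ann$MAPINFO[idx])
    brk <- c(0L, which(gaps > window), length(idx))
    for (i in seq_len(length(brk) - 1L)) {
      chain <- idx[(brk[i] + 1L):brk[i + 1L]]
      if (length(chain) >= min_cpgs) {
        regions[[length(regions) + 1L]] <- list(
          region = sprintf("chr%s:%d-%d", cc, min(ann$MAPINFO[chain]),
                           max(ann$MAPINFO[chain])),
          type = "chain", chr = cc, probes = sort(sig_probes[chain]))
      }
    }
  }
  if (!length(regions)) {
    return(data.frame(region = character(0), type = character(0),
                      chr = character(0), probes = I(list())))
  }
  out <- data.frame(
    region = vapply(regions, `[[`, character(1), "region"),
    type = vapply(regions, `[[`, character(1), "type"),
    chr = as.character(vapply(regions, `[[`, character(1), "chr")),
    stringsAsFactors = FALSE
  )
  out$probes <- I(lapply(regions, `[[`, "probes"))
  dup <- duplicated(vapply(out$probes, paste, character(1), collapse = ","))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster patients into methylation groups on a region's CpGs
#'
#' Hierarchical clustering (Euclidean distance, Ward linkage) of patients on
#' the region's CpG beta-values, cut at `k` groups and relabeled
#' hypo / intermediate / hyper by ascending mean beta. `k` is reduced when
#' fewer distinct profiles (or patients) exist.
#'
#' @param region_beta CpGs-by-patients beta matrix for the region.
#' @param k Number of groups, default 3.
#' @return Named character vector patient -> group label.
#' @export
assign_methylation_groups <- function(region_beta, k = 3L) {
  x <- t(as.matrix(region_beta))  # patients x CpGs
  n_distinct <- nrow(unique(x))
  kk <- min(k, n_distinct, nrow(x))
  if (kk < k) message("k reduced to ", kk, " (fewer distinct profiles)")
  if (kk == 1L) {
    return(stats::setNames(rep("intermediate", nrow(x)), rownames(x)))
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  cl <- stats::cutree(hc, k = kk)
  means <- tapply(rowMeans(x), cl, mean)
  ord <- order(means)
  labels <- if (kk == 3L) c("hypo", "intermediate", "hyper") else
    c("hypo", "hyper")[seq_len(kk)]
  lab_of <- stats::setNames(labels, names(means)[ord])
  stats::setNames(unname(lab_of[as.character(cl)]), rownames(x))
}

# left-limit Kaplan-Meier and cause-specific CIF of one group evaluated at
# given times
km_cif_left <- function(time, event, cause, eval_times) {
  ut <- sort(unique(time))
  S <- 1; F1 <- 0
  S_path <- numeric(length(ut)); F_path <- numeric(length(ut))
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_at <- sum(time >= t)
    d_all <- sum(time == t & event != "censored")
    d_c <- sum(time == t & event == cause)
    F1 <- F1 + if (n_at > 0) S * d_c / n_at else 0
    S <- S * if (n_at > 0) (1 - d_all / n_at) else 1
    S_path[i] <- S; F_path[i] <- F1
  }
  idx <- findInterval(eval_times - 1e-12, ut)  # strictly-before index
  S_left <- c(1, S_path)[idx + 1L]
  F_left <- c(0, F_path)[idx + 1L]
  list(S = S_left, F1 = F_left)
}

#' Cumulative incidence function under competing risks
#'
#' Aalen-Johansen-type estimator:
#' `CIF(t) = sum over event times t_i <= t of S(t_i-) * d_cause_i / n_i`,
#' where `S` is the all-cause Kaplan-Meier estimate.
#'
#' @param time Follow-up times.
#' @param event Event labels; `"censored"` marks censoring, any other label
#'   is an event cause.
#' @param cause The cause of interest, default `"relapse"`.
#' @return Data frame with `time` (event times of any cause, sorted) and
#'   `cif`, the step-function values at those times.
#' @export
cumulative_incidence <- function(time, event, cause = "relapse") {
  stopifnot(length(time) == length(event), all(time > 0))
  ut <- sort(unique(time[event != "censored"]))
  S <- 1; F1 <- 0
  out <- data.frame(time = ut, cif = NA_real_)
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_at <- sum(time >= t)
    d_all <- sum(time == t & event != "censored")
    d_c <- sum(time == t & event == cause)
    F1 <- F1 + S * d_c / n_at
    S <- S * (1 - d_all / n_at)
    out$cif[i] <- F1
  }
  out
}

#' Gray's K-sample test for equality of cumulative incidence functions
#'
#' Tests whether the cause-specific cumulative incidence differs between
#' groups in the presence of competing risks (rho = 0 weighting). The group
#' scores accumulate observed-minus-expected subdistribution-hazard
#' increments over the event times of the cause of interest, with
#' subdistribution risk sets `R_k(t) = Y_k(t) (1 - F_k(t-)) / S_k(t-)` that
#' retain prior competing-cause failures, and the covariance uses the
#' hypergeometric form on the modified risk sets, inverted by pseudo-inverse.
#' With no competing events present the statistic reduces exactly to the
#' log-rank chi-square.
#'
#' @param time Follow-up times.
#' @param event Event labels; `"censored"` marks censoring.
#' @param group Group labels (length of `time`); groups without observations
#'   are dropped with a warning.
#' @param cause Cause of interest, default `"relapse"`.
#' @return List with `statistic`, `df` and `p`.
#' @export
gray_test <- function(time, event, group, cause = "relapse") {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.character(group)
  keep_groups <- unique(group)
  empty <- vapply(keep_groups, function(g) sum(group == g) == 0, logical(1))
  if (any(empty)) {
    warning("dropping empty group(s): ", paste(keep_groups[empty], collapse = ", "))
    keep_groups <- keep_groups[!empty]
  }
  groups <- sort(keep_groups)
  K <- length(groups)
  if (K < 2) stop("need at least 2 non-empty groups")
  if (!any(event == cause)) stop("no events of the cause of interest")

  evt <- sort(unique(time[event == cause]))
  ne <- length(evt)
  Rk <- matrix(0, nrow = ne, ncol = K)
  d1k <- matrix(0, nrow = ne, ncol = K)
  for (k in seq_len(K)) {
    in_k <- group == groups[k]
    tk <- time[in_k]; ek <- event[in_k]
    lim <- km_cif_left(tk, ek, cause, evt)
    Yk <- vapply(evt, function(t) sum(tk >= t), numeric(1))
    w <- ifelse(lim$S > 0, (1 - lim$F1) / lim$S, 0)
    Rk[, k] <- Yk * w
    d1k[, k] <- vapply(evt, function(t) sum(tk == t & ek == cause), numeric(1))
  }
  Rtot <- rowSums(Rk)
  dtot <- rowSums(d1k)
  ok <- Rtot > 0
  z <- colSums(d1k[ok, , drop = FALSE] -
                 Rk[ok, , drop = FALSE] * (dtot / Rtot)[ok])
  V <- matrix(0, K, K)
  for (i in which(ok)) {
    p <- Rk[i, ] / Rtot[i]
    mult <- if (Rtot[i] > 1) dtot[i] * (Rtot[i] - dtot[i]) / (Rtot[i] - 1) else 0
    V <- V + mult * (diag(p) - tcrossprod(p))
  }
  Vinv <- pseudo_inverse(V)
  stat <- as.numeric(t(z) %*% Vinv %*% z)
  df <- K - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

pseudo_inverse <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, 1e-300)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Label patients for relapse-free-survival classification
#'
#' Training classes: `relapse` for patients with a relapse event at any
#' follow-up; `remission` for patients censored event-free after at least
#' `min_followup` years; all other patients (competing events, or censored
#' earlier) are `excluded` from training but can still be scored.
#'
#' @param outcomes Outcome data frame (see [simulate_outcomes()]): columns
#'   `patient_id`, `time`, `event`.
#' @param min_followup Minimum event-free follow-up for the remission class,
#'   default 5 years.
#' @return Named character vector patient -> class label.
#' @export
relapse_class_labels <- function(outcomes, min_followup = 5) {
  lab <- ifelse(outcomes$event == "relapse", "relapse",
                ifelse(outcomes$event == "censored" &
                         outcomes$time >= min_followup,
                       "remission", "excluded"))
  stats::setNames(lab, outcomes$patient_id)
}

#' Relapse-free-survival analysis of one signature in one stratum
#'
#' End-to-end survival screen: trains and evaluates the NSC classifier by
#' repeated cross-validation, permutation-tests the signature AUC, scores
#' individual CpGs with permutation p-values, aggregates significant CpGs
#' (p < `cpg_alpha`) into gene / 50-kb regions, clusters patients into
#' methylation groups on each region, and compares the groups' relapse
#' cumulative incidence with Gray's test.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param sheet Sample sheet.
#' @param outcomes Outcome table.
#' @param signature Character vector of signature CpG ids.
#' @param annotation Probe annotation.
#' @param subtype Optional subtype restriction; `NULL` uses all patients.
#' @param treatment Optional treatment-group restriction.
#' @param folds,repeats,n_delta,nested_folds CV geometry (see
#'   [repeated_cv_auc()]).
#' @param auc_perms Permutations for the signature AUC test.
#' @param cpg_perms Permutations for per-CpG scoring.
#' @param cpg_alpha Per-CpG significance threshold for region aggregation,
#'   default 0.05.
#' @param min_patients,min_relapses Stratum size gates; smaller strata return
#'   `NULL` with a message.
#' @param seed Integer seed.
#' @return List with `labels`, `cv` (AUC results), `signature_test`,
#'   `cpg_scores`, `regions` (with per-region methylation groups and Gray's
#'   test), or `NULL` when the stratum is too small.
#' @export
survival_screen <- function(beta, sheet, outcomes, signature, annotation,
                            subtype = NULL, treatment = NULL,
                            folds = 5, repeats = 10, n_delta = 15,
                            nested_folds = 3, auc_perms = 100,
                            cpg_perms = 100, cpg_alpha = 0.05,
                            min_patients = 10, min_relapses = 3, seed = 1L) {
  dg <- sheet[sheet$role == "ALL" & sheet$phase == "diagnosis", ]
  if (!is.null(subtype)) dg <- dg[dg$subtype == subtype, ]
  if (!is.null(treatment)) dg <- dg[dg$treatment == treatment, ]
  out <- outcomes[match(dg$patient_id, outcomes$patient_id), ]
  labels <- relapse_class_labels(out)
  train <- labels != "excluded"
  n_rel <- sum(labels == "relapse")
  if (nrow(dg) < min_patients || n_rel < min_relapses ||
      sum(labels == "remission") < 2) {
    message("stratum skipped: ", nrow(dg), " patients, ", n_rel, " relapses")
    return(NULL)
  }
  sig <- intersect(signature, rownames(beta))
  X <- t(beta[sig, dg$sample_id, drop = FALSE])
  rownames(X) <- dg$patient_id
  Xtr <- X[train, , drop = FALSE]
  ytr <- labels[train]

  cv <- repeated_cv_auc(Xtr, ytr, positive = "relapse", folds = folds,
                        repeats = repeats, n_delta = n_delta,
                        nested_folds = nested_folds, seed = seed)
  sig_test <- permutation_test_signature(Xtr, ytr, B = auc_perms,
                                         positive = "relapse", folds = folds,
                                         repeats = max(2, repeats %/% 5),
                                         n_delta = n_delta,
                                         nested_folds = nested_folds,
                                         seed = seed)
  scores <- score_cpgs(Xtr, ytr, positive = "relapse", folds = folds,
                       repeats = max(2, repeats %/% 5), B = cpg_perms,
                       n_delta = n_delta, nested_folds = nested_folds,
                       seed = seed)
  sig_cpgs <- scores$probe[scores$p < cpg_alpha]
  regions <- aggregate_regions(sig_cpgs, annotation)
  if (nrow(regions)) {
    groups_list <- vector("list", nrow(regions))
    gray <- data.frame(statistic = rep(NA_real_, nrow(regions)),
                       df = NA_integer_, p = NA_real_)
    for (i in seq_len(nrow(regions))) {
      rb <- beta[regions$probes[[i]], dg$sample_id, drop = FALSE]
      colnames(rb) <- dg$patient_id
      grp <- assign_methylation_groups(rb)
      groups_list[[i]] <- grp
      gt <- tryCatch(gray_test(out$time, out$event, grp[out$patient_id]),
                     error = function(e) NULL)
      if (!is.null(gt)) {
        gray$statistic[i] <- gt$statistic
        gray$df[i] <- gt$df
        gray$p[i] <- gt$p
      }
    }
    regions$gray_stat <- gray$statistic
    regions$gray_df <- gray$df
    regions$gray_p <- gray$p
    regions$groups <- I(groups_list)
  }
  list(labels = labels, cv = cv, signature_test = sig_test,
       cpg_scores = scores, regions = regions)
}
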