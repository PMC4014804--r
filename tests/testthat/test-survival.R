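test_that("NSC standardized differences match a hand evaluation", {
  # 2 features, 6 samples, 2 classes of 3
  X <- rbind(c(1, 10), c(2, 11), c(3, 12),
             c(7, 10), c(8, 13), c(9, 10))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 3)
  fit <- nsc_train(X, y, delta = 0)
  n <- 6; K <- 2
  overall <- colMeans(X)
  cent_a <- colMeans(X[1:3, ]); cent_b <- colMeans(X[4:6, ])
  s <- sqrt((colSums(sweep(X[1:3, ], 2, cent_a)^2) +
               colSums(sweep(X[4:6, ], 2, cent_b)^2)) / (n - K))
  s0 <- stats::median(s)
  mk <- sqrt(1 / 3 - 1 / 6)
  d_a <- (cent_a - overall) / (mk * (s + s0))
  expect_equal(fit$d[1, ], d_a, tolerance = 1e-12)
  expect_equal(fit$s0, s0)
  # delta = 0 keeps d unshrunken
  expect_equal(fit$d, fit$d_shrunk)
})

test_that("NSC at delta 0 equals the diagonal nearest-centroid rule", {
  set.seed(41)
  X <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 1.5), 20))
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("a", "b"), each = 20)
  fit <- nsc_train(X, y, delta = 0, priors = c(0.5, 0.5))
  Xnew <- matrix(rnorm(30, 0.75), 10)
  colnames(Xnew) <- colnames(X)
  pred <- nsc_predict(fit, Xnew)
  # diagonal nearest centroid with pooled (s_i + s0) scaling
  disc <- sapply(1:2, function(k) {
    rowSums(sweep(Xnew, 2, fit$centroids[k, ])^2 / rep((fit$s + fit$s0)^2,
                                                       each = nrow(Xnew)))
  })
  expect_equal(pred$class, c("a", "b")[apply(disc, 1, which.min)])
})

test_that("total shrinkage collapses centroids and predicts the prior argmax", {
  set.seed(43)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("a", "b"), c(14, 6))
  fit <- nsc_train(X, y, delta = max(abs(nsc_train(X, y)$d)) + 1)
  expect_true(all(abs(fit$d_shrunk) == 0))
  expect_equal(fit$shrunken_centroids[1, ], fit$shrunken_centroids[2, ])
  pred <- nsc_predict(fit, X)
  expect_true(all(pred$class == "a"))  # majority class via priors
})

test_that("a shrunken class centroid is classified into its class", {
  set.seed(44)
  X <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 2), 10))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c("a", "b"), each = 10)
  fit <- nsc_train(X, y, delta = 0.5, priors = c(0.5, 0.5))
  pred <- nsc_predict(fit, fit$shrunken_centroids)
  expect_equal(pred$class, c("a", "b"))
  expect_error(nsc_train(X[c(1, 11:20), ], y[c(1, 11:20)]), "at least 2")
})

test_that("AUC equals the brute-force pairwise comparison", {
  set.seed(45)
  scores <- rnorm(30)
  labels <- rep(c("relapse", "remission"), each = 15)
  brute <- mean(outer(scores[1:15], scores[16:30],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_score(scores, labels, "relapse"), brute)
  # ties counted one half
  s2 <- c(1, 1, 2); l2 <- c("relapse", "remission", "remission")
  expect_equal(auc_score(s2, l2, "relapse"), 0.25)
  # invariance under strictly monotone transforms
  expect_equal(auc_score(exp(scores), labels, "relapse"),
               auc_score(scores, labels, "relapse"))
  # separable scores give AUC 1
  expect_equal(auc_score(c(5, 6, 1, 2), c("relapse", "relapse",
                                          "remission", "remission"),
                         "relapse"), 1)
})

test_that("repeated CV finds separable structure and stays at chance on noise", {
  set.seed(47)
  X <- rbind(matrix(rnorm(200, 0, 0.3), 20), matrix(rnorm(200, 1, 0.3), 20))
  colnames(X) <- paste0("f", 1:10)
  y <- rep(c("remission", "relapse"), each = 20)
  cv <- repeated_cv_auc(X, y, repeats = 5, n_delta = 10, seed = 1)
  expect_gte(cv$auc, 0.95)
  # shuffled labels: chance performance
  aucs <- vapply(1:6, function(s) {
    set.seed(s + 100)
    repeated_cv_auc(X, sample(y), repeats = 3, n_delta = 10,
                    seed = s)$auc
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.25))  # single-seed null spread
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("signature permutation test flags planted signal and floors at 1/(B+1)", {
  set.seed(49)
  X <- rbind(matrix(rnorm(120, 0, 0.4), 15), matrix(rnorm(120, 1, 0.4), 15))
  colnames(X) <- paste0("f", 1:8)
  y <- rep(c("remission", "relapse"), each = 15)
  pt <- permutation_test_signature(X, y, B = 40, repeats = 2, seed = 3)
  expect_lte(pt$p, 0.05)
  expect_gte(pt$p, 1 / 41)
})

test_that("CpG scores shrink monotonically and rank planted features on top", {
  set.seed(51)
  X <- cbind(matrix(rnorm(160, 0, 1), 40, 4),            # noise
             rbind(matrix(rnorm(60, 0, 0.3), 20),
                   matrix(rnorm(60, 1.2, 0.3), 20)))     # signal
  colnames(X) <- paste0("f", 1:7)
  y <- rep(c("remission", "relapse"), each = 20)
  fit <- nsc_train(X, y)
  d1 <- abs(methylall:::nsc_shrink(fit, 0.3)$d_shrunk)
  d2 <- abs(methylall:::nsc_shrink(fit, 0.6)$d_shrunk)
  expect_true(all(d2 <= d1 + 1e-12))  # doubling shrinkage never raises a score
  sc <- score_cpgs(X, y, repeats = 3, B = 60, seed = 5)
  top3 <- sc$probe[order(-sc$score)][1:3]
  expect_setequal(top3, c("f5", "f6", "f7"))
  expect_true(all(sc$p[sc$probe %in% top3] < 0.05))
  # fully shrunken features carry p near 1
  expect_true(all(sc$p[sc$score == 0] > 0.5))
})

test_that("region aggregation implements the gene and 50-kb chain rules", {
  ann <- data.frame(
    IlmnID = paste0("c", 1:7),
    CHR = c("1", "1", "1", "2", "2", "3", "3"),
    MAPINFO = c(1000, 31000, 81000, 5000, 65000, 1000, 2000),
    UCSC_RefGene_Name = c("", "", "", "gX", "gX", "gY;gZ", "gY")
  )
  regs <- aggregate_regions(paste0("c", 1:7), ann, window = 50000)
  # chain on chr1: c1-c2 (30 kb), c3 joins via 50-kb gap from c2
  chain1 <- regs[regs$type == "chain" & regs$chr == "1", ]
  expect_equal(chain1$probes[[1]], c("c1", "c2", "c3"))
  # gene rule bridges the 60-kb gap on chr2
  gx <- regs[regs$region == "gX", ]
  expect_equal(gx$probes[[1]], c("c4", "c5"))
  # gY region and the chr3 chain hold the same CpGs: merged once
  expect_equal(sum(vapply(regs$probes, identical, logical(1),
                          c("c6", "c7"))), 1L)
  # chains below min size are dropped
  regs2 <- aggregate_regions(c("c1", "c3"), ann, window = 50000)
  expect_false(any(regs2$type == "chain" & regs2$chr == "1" &
                     lengths(regs2$probes) < 2))
})

test_that("methylation groups recover planted profiles and label by mean beta", {
  set.seed(53)
  centers <- c(0.1, 0.5, 0.9)
  rb <- sapply(rep(centers, each = 10), function(m) rnorm(4, m, 0.03))
  rownames(rb) <- paste0("cg", 1:4)
  colnames(rb) <- paste0("pt", 1:30)
  grp <- assign_methylation_groups(rb)
  expect_equal(unname(grp[1:10]), rep("hypo", 10))
  expect_equal(unname(grp[11:20]), rep("intermediate", 10))
  expect_equal(unname(grp[21:30]), rep("hyper", 10))
  # invariance to column order
  perm <- sample(30)
  grp2 <- assign_methylation_groups(rb[, perm])
  expect_equal(grp2[colnames(rb)], grp)
  # identical rows: one group
  flat <- matrix(0.5, 4, 6, dimnames = list(paste0("cg", 1:4), paste0("p", 1:6)))
  expect_equal(unique(unname(suppressMessages(assign_methylation_groups(flat)))),
               "intermediate")
})

test_that("cumulative incidence matches hand computation and reduces to 1-KM", {
  # n=4: cause1 at t=1, cause2 at t=2, cause1 at t=3, censored at t=4
  ci <- cumulative_incidence(c(1, 2, 3, 4),
                             c("relapse", "other_event", "relapse", "censored"))
  expect_equal(ci$cif[ci$time == 1], 0.25)
  expect_equal(ci$cif[ci$time == 3], 0.50)
  expect_true(all(diff(ci$cif) >= 0))
  expect_true(all(ci$cif <= 1))
  # no competing events, no censoring: CIF = 1 - KM
  set.seed(55)
  tt <- rexp(40, 0.3)
  ci2 <- cumulative_incidence(tt, rep("relapse", 40))
  km <- cumprod(1 - 1 / (40:1))
  expect_equal(ci2$cif, 1 - km[rank(sort(tt))], tolerance = 1e-12)
})

test_that("cumulative incidence agrees with the survival package estimator", {
  skip_if_not_installed("survival")
  set.seed(56)
  n <- 80
  tt <- rexp(n, 0.1); cc <- rexp(n, 0.06); cn <- rexp(n, 0.05)
  time <- pmin(tt, cc, cn)
  ev <- ifelse(time == tt, "relapse", ifelse(time == cc, "other_event",
                                             "censored"))
  ci <- cumulative_incidence(time, ev)
  st <- factor(ifelse(ev == "censored", "censor", ev),
               levels = c("censor", "relapse", "other_event"))
  fit <- survival::survfit(survival::Surv(time, st) ~ 1)
  aj <- fit$pstate[, which(fit$states == "relapse")]
  idx <- match(ci$time, fit$time)
  expect_equal(ci$cif, aj[idx], tolerance = 1e-9)
})

test_that("Gray's test equals the log-rank without competing events", {
  skip_if_not_installed("survival")
  set.seed(57)
  for (i in 1:5) {
    n <- 60 + 10 * i
    tt <- rexp(n, 0.1); cn <- rexp(n, 0.05)
    time <- pmin(tt, cn)
    ev <- ifelse(tt <= cn, "relapse", "censored")
    grp <- sample(rep(c("a", "b", "c"), length.out = n))
    gt <- gray_test(time, ev, grp)
    # oracle 1: independently implemented log-rank
    expect_lt(abs(gt$statistic - brute_logrank(time, ev == "relapse", grp)),
              1e-6)
    # oracle 2: the survival package
    sd <- survival::survdiff(survival::Surv(time, ev == "relapse") ~ grp)
    expect_lt(abs(gt$statistic - sd$chisq), 1e-6)
  }
})

test_that("Gray's test tracks cmprsk under competing risks and handles edge cases", {
  skip_if_not_installed("cmprsk")
  set.seed(59)
  for (i in 1:5) {
    n <- 100
    tt <- rexp(n, 0.08); cc <- rexp(n, 0.05); cn <- rexp(n, 0.05)
    time <- pmin(tt, cc, cn)
    ev <- ifelse(time == tt, "relapse",
                 ifelse(time == cc, "other_event", "censored"))
    grp <- sample(rep(c("a", "b"), each = n / 2))
    gt <- gray_test(time, ev, grp)
    ci <- cmprsk::cuminc(time, ifelse(ev == "relapse", 1,
                                      ifelse(ev == "other_event", 2, 0)), grp)
    expect_lt(abs(gt$statistic - ci$Tests["1", "stat"]), 0.25)
    expect_lt(abs(gt$p - ci$Tests["1", "pv"]), 0.05)
  }
  # identical event tables across groups: statistic 0
  time <- rep(c(1, 2, 3, 4), 2)
  ev <- rep(c("relapse", "censored", "relapse", "censored"), 2)
  grp <- rep(c("a", "b"), each = 4)
  gt0 <- gray_test(time, ev, grp)
  expect_lt(gt0$statistic, 1e-10)
  expect_equal(gt0$p, 1)
  expect_error(gray_test(time, rep("censored", 8), grp), "no events")
})

test_that("survival screen recovers a planted prognostic region end to end", {
  cfg <- survival_cohort_config(seed = 103)
  sim <- simulate_all(cfg)
  pg <- sim$truth$prognostic$regions[[1]]
  scr <- suppressMessages(survival_screen(
    sim$beta, sim$sheet, sim$outcomes,
    signature = c(sim$truth$subtype_unique$probe, pg$probes),
    annotation = sim$annotation, subtype = "t(12;21)",
    repeats = 6, auc_perms = 20, cpg_perms = 80, seed = 7))
  expect_false(is.null(scr))
  hit <- vapply(scr$regions$probes,
                function(p) length(intersect(p, pg$probes)) >= 2, logical(1))
  expect_true(any(hit))
  expect_lt(min(scr$regions$gray_p[hit]), 0.05)
  # strata below the size gates are skipped
  expect_message(
    out <- survival_screen(sim$beta, sim$sheet, sim$outcomes,
                           signature = pg$probes,
                           annotation = sim$annotation, subtype = "t(12;21)",
                           min_patients = 1000, seed = 1),
    "skipped")
  expect_null(out)
})
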