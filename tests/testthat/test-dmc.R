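test_that("rank-sum p matches exact enumeration on small samples", {
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)  # 2/20 assignments
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(3:5, 1))
    b <- rnorm(sample(3:5, 1), mean = runif(1, -1, 1))
    expect_equal(ranksum_test(a, b), enum_ranksum_p(a, b), tolerance = 1e-12)
  }
  expect_equal(ranksum_test(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(ranksum_test(rep(2, 5), rep(2, 4)), 1)  # degenerate
})

test_that("large-sample rank-sum approximation tracks the exact law", {
  set.seed(3)
  diffs <- replicate(30, {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    exact <- enum_ranksum_p(a, b)
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    abs(exact - approx)
  })
  expect_lt(stats::median(diffs), 0.005)
  expect_lt(max(diffs), 0.02)
})

test_that("signed-rank p matches exact enumeration of sign patterns", {
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5)), 0.0625)  # 2/32
  set.seed(5)
  for (i in 1:20) {
    d <- rnorm(sample(5:8, 1), mean = runif(1, -0.5, 0.5))
    expect_equal(signed_rank_test(d), enum_signedrank_p(d), tolerance = 1e-12)
  }
  # strong planted shift, large n: decisively significant
  d <- rnorm(27, 0.3, 0.05)
  expect_lt(signed_rank_test(d), 1e-4)
  expect_equal(signed_rank_test(rep(0, 10)), 1)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("reference SD filter uses a strict threshold", {
  b <- rbind(
    flat = c(0.10, 0.10, 0.10),
    wild = c(0.0, 0.5, 1.0),
    edge = c(0.4, 0.5, 0.6)  # sd = 0.1 exactly
  )
  colnames(b) <- paste0("r", 1:3)
  excluded <- reference_sd_filter(b, paste0("r", 1:3))
  expect_equal(excluded, "wild")
  expect_error(reference_sd_filter(b, "r1"))
})

test_that("row-wise rank-sum agrees with wilcox.test on random rows", {
  set.seed(21)
  m <- matrix(runif(50 * 30), nrow = 50)
  rownames(m) <- paste0("p", 1:50)
  # duplicate some values to create ties
  m[1:10, 2] <- m[1:10, 1]
  p_rows <- methylall:::row_ranksum_p(m, 1:12, 13:30)
  p_ref <- apply(m, 1, function(v) {
    suppressWarnings(stats::wilcox.test(v[1:12], v[13:30],
                                        exact = FALSE, correct = TRUE)$p.value)
  })
  expect_equal(unname(p_rows), unname(p_ref), tolerance = 1e-12)
  # small-n path against the scalar operation
  p_small <- methylall:::row_ranksum_p(m[, 1:20], 1:10, 11:20)
  p_scalar <- apply(m[, 1:20], 1, function(v) ranksum_test(v[1:10], v[11:20]))
  expect_equal(unname(p_small), unname(p_scalar), tolerance = 1e-12)
})

test_that("planted DMCs are called and sub-threshold effects are not", {
  # toy: 2 planted at delta 0.5, 1 planted at 0.15 (below the gate), rest null
  set.seed(31)
  n_a <- 10; n_b <- 10
  kappa <- 200
  draw <- function(mu, n) rbeta(n, mu * kappa, (1 - mu) * kappa)
  mk_row <- function(mu_a, mu_b) c(draw(mu_a, n_a), draw(mu_b, n_b))
  beta <- rbind(
    dmc1 = mk_row(0.7, 0.2), dmc2 = mk_row(0.1, 0.6),
    small = mk_row(0.35, 0.2),
    null1 = mk_row(0.5, 0.5), null2 = mk_row(0.9, 0.9)
  )
  colnames(beta) <- c(paste0("S", 1:n_a), paste0("R", 1:n_b))
  sheet <- data.frame(
    sample_id = colnames(beta),
    patient_id = colnames(beta),
    role = rep(c("ALL", "reference"), c(n_a, n_b)),
    cell_type = rep(c(NA, "BM"), c(n_a, n_b)),
    subtype = rep(c("HeH", NA), c(n_a, n_b)),
    phase = rep(c("diagnosis", "reference"), c(n_a, n_b)),
    treatment = NA, lineage = rep(c("B", NA), c(n_a, n_b))
  )
  tab <- call_dmcs(beta, sheet, "HeH")
  expect_setequal(tab$probe[tab$is_dmc], c("dmc1", "dmc2"))
  expect_equal(tab$direction[tab$probe == "dmc1"], "hyper")
  expect_equal(tab$direction[tab$probe == "dmc2"], "hypo")
  # direction always equals the sign of the recomputed mean difference
  md <- rowMeans(beta[, 1:n_a]) - rowMeans(beta[, -(1:n_a)])
  expect_equal(tab$direction, unname(ifelse(md > 0, "hyper", "hypo")))
  expect_error(call_dmcs(beta, sheet, "nope"), "valid subtypes")
})

test_that("null cohorts yield (almost) no DMCs and planted cohorts are recovered", {
  # null: no planted signals at all
  cfg0 <- sim_config(n_cpg = 2000, n_per_subtype = c("HeH" = 12),
                     n_reference = c(BM = 6, CD19 = 5, CD3 = 0, CD34 = 5),
                     n_relapse_pairs = 0, frac_constitutive = 0,
                     frac_subtype_unique = 0, frac_relapse = 0,
                     prognostic_regions = list(), n_corr_genes = 0, seed = 9)
  sim0 <- simulate_cohort(cfg0)
  tab0 <- call_dmcs(sim0$beta, sim0$sheet, "HeH")
  expect_lte(sum(tab0$is_dmc), 1)
  # planted: near-perfect sensitivity at delta 0.5
  sim1 <- simulate_cohort(small_cohort_config(seed = 10))
  tab1 <- call_dmcs(sim1$beta, sim1$sheet, "HeH")
  planted <- c(sim1$truth$constitutive$probe,
               sim1$truth$subtype_unique$probe[
                 sim1$truth$subtype_unique$subtype == "HeH"])
  called <- tab1$probe[tab1$is_dmc]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.95)
  # precision: nearly everything called was planted
  expect_gte(length(intersect(called, planted)) / length(called), 0.95)
})

test_that("paired relapse DMCs recover the planted relapse signature", {
  sim <- simulate_cohort(small_cohort_config(seed = 12))
  tab <- call_relapse_dmcs(sim$beta, sim$sheet)
  planted <- sim$truth$relapse$probe
  called <- tab$probe[tab$is_dmc]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.9)
  expect_gte(length(intersect(called, planted)) / max(length(called), 1), 0.9)
  # direction bookkeeping against the truth set
  dirs <- tab$direction[match(planted, tab$probe)]
  hit <- planted %in% called
  expect_true(all(dirs[hit] == sim$truth$relapse$direction[hit]))
})

test_that("signature assembly follows the set algebra and direction rules", {
  mk <- function(probes, dirs, all_probes = paste0("p", 1:6)) {
    data.frame(probe = all_probes,
               direction = ifelse(all_probes %in% probes,
                                  dirs[match(all_probes, probes)], "hyper"),
               is_dmc = all_probes %in% probes)
  }
  tabs <- list(
    A = mk(c("p1", "p2", "p3"), c("hyper", "hyper", "hyper")),
    B = mk(c("p1", "p2"), c("hyper", "hyper")),
    C = mk(c("p1", "p4"), c("hyper", "hypo"))
  )
  sig <- build_signatures(tabs)
  expect_equal(sig$constitutive$probe, "p1")
  expect_setequal(sig$unique$probe, c("p3", "p4"))
  expect_equal(sig$unique$subtype[sig$unique$probe == "p3"], "A")
  # direction conflict blocks constitutive membership
  tabs$B$direction[tabs$B$probe == "p1"] <- "hypo"
  sig2 <- build_signatures(tabs)
  expect_equal(nrow(sig2$constitutive), 0)
  sig3 <- build_signatures(tabs, require_direction = FALSE)
  expect_equal(sig3$constitutive$probe, "p1")
  expect_error(build_signatures(tabs["A"]), "at least 2")
})

test_that("recovered signatures match the planted design (Jaccard >= 0.9)", {
  sim <- simulate_cohort(small_cohort_config(seed = 14))
  subtypes <- c("HeH", "T-ALL")
  tabs <- lapply(subtypes, function(s) call_dmcs(sim$beta, sim$sheet, s))
  names(tabs) <- subtypes
  sig <- build_signatures(tabs)
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gte(jaccard(sig$constitutive$probe, sim$truth$constitutive$probe), 0.9)
  for (s in subtypes) {
    expect_gte(jaccard(sig$unique$probe[sig$unique$subtype == s],
                       sim$truth$subtype_unique$probe[
                         sim$truth$subtype_unique$subtype == s]), 0.9)
  }
})
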