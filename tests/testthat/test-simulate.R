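test_that("cohort dimensions, value range and seed contract hold", {
  cfg <- sim_config(n_cpg = 1000,
                    n_per_subtype = c("HeH" = 20, "T-ALL" = 20),
                    n_reference = c(BM = 10, CD19 = 10, CD3 = 10, CD34 = 0),
                    n_relapse_pairs = 0, seed = 4)
  sim <- simulate_cohort(cfg)
  expect_equal(dim(sim$beta), c(1000, 40 + 30))
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  expect_equal(nrow(sim$annotation), 1000)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$beta, sim2$beta)
  expect_identical(sim$truth$constitutive, sim2$truth$constitutive)
})

test_that("planted effects shift group means by the configured delta", {
  cfg <- sim_config(n_cpg = 2000,
                    n_per_subtype = c("HeH" = 20, "T-ALL" = 20),
                    n_reference = c(BM = 10, CD19 = 10, CD3 = 10, CD34 = 10),
                    n_relapse_pairs = 0, beta_precision = 400, seed = 6)
  sim <- simulate_cohort(cfg)
  all_ids <- sim$sheet$sample_id[sim$sheet$role == "ALL"]
  ref_ids <- sim$sheet$sample_id[sim$sheet$role == "reference"]
  tr <- sim$truth$constitutive
  db <- rowMeans(sim$beta[tr$probe, all_ids]) - rowMeans(sim$beta[tr$probe, ref_ids])
  signed <- db * ifelse(tr$direction == "hyper", 1, -1)
  expect_lt(max(abs(signed - 0.5)), 0.05)
  # truth directions match the empirical sign
  expect_true(all(sign(db) == ifelse(tr$direction == "hyper", 1, -1)))
})

test_that("planted truth sets are disjoint and present in the annotation", {
  sim <- simulate_cohort(small_cohort_config(seed = 8))
  sets <- list(sim$truth$constitutive$probe, sim$truth$subtype_unique$probe,
               sim$truth$relapse$probe,
               unlist(lapply(sim$truth$prognostic$regions, `[[`, "probes")))
  all_ids <- unlist(sets)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_true(all(all_ids %in% sim$annotation$IlmnID))
  # planted probes survive the analysis filter (autosomal, SNP-free)
  expect_true(all(all_ids %in% filter_probes(sim$annotation)))
})

test_that("contradictory configurations are rejected", {
  expect_error(sim_config(frac_constitutive = 0.6, frac_subtype_unique = 0.06,
                          frac_relapse = 0.1), "sum to more than 1")
  expect_error(sim_config(effect_delta = 1.2), "effect_delta")
  expect_error(sim_config(beta_precision = -1), "beta_precision")
  expect_error(sim_config(typeII_compression = 0), "typeII_compression")
})

test_that("doubling the group size shrinks the delta-beta standard error", {
  se_of <- function(n_per, seed) {
    cfg <- sim_config(n_cpg = 1500, n_per_subtype = c("HeH" = n_per),
                      n_reference = c(BM = n_per, CD19 = 0, CD3 = 0, CD34 = 0),
                      n_relapse_pairs = 0, frac_constitutive = 0.1,
                      frac_subtype_unique = 0, frac_relapse = 0,
                      prognostic_regions = list(), seed = seed)
    sim <- simulate_cohort(cfg)
    all_ids <- sim$sheet$sample_id[sim$sheet$role == "ALL"]
    ref_ids <- sim$sheet$sample_id[sim$sheet$role == "reference"]
    tr <- sim$truth$constitutive
    db <- rowMeans(sim$beta[tr$probe, all_ids]) -
      rowMeans(sim$beta[tr$probe, ref_ids])
    stats::sd(db * ifelse(tr$direction == "hyper", 1, -1))
  }
  se_small <- mean(vapply(1:3, function(s) se_of(10, s), numeric(1)))
  se_big <- mean(vapply(1:3, function(s) se_of(40, s + 10), numeric(1)))
  expect_lt(se_big / se_small, 0.65)  # ~0.5 expected, Monte-Carlo slack
})

test_that("expression coupling obeys the sign and correlation contracts", {
  sim <- simulate_cohort(small_cohort_config(seed = 16))
  expr <- simulate_expression(sim)
  shared <- intersect(colnames(sim$beta), colnames(expr))
  tg <- sim$truth$correlated_genes
  rs <- vapply(seq_len(nrow(tg)), function(i) {
    stats::cor(sim$beta[tg$probe[i], shared], expr[tg$gene[i], shared])
  }, numeric(1))
  expect_true(all(sign(rs) == tg$sign))
  expect_gte(mean(abs(rs) >= 0.7), 0.9)
})

test_that("outcome generation respects its limiting regimes", {
  cfg0 <- survival_cohort_config(seed = 20, n_patients = 40, n_cpg = 300)
  sim <- simulate_cohort(cfg0)
  # heavy censoring: everything censored almost immediately
  cfg_c <- cfg0
  cfg_c$censoring_rate <- 1e6
  out_c <- simulate_outcomes(sim, cfg_c)
  expect_true(all(out_c$event == "censored"))
  expect_lt(max(out_c$time), 0.001)
  # all hazard ratios 1: groups carry no signal (Gray p well above tiny)
  cfg_n <- cfg0
  cfg_n$prognostic_regions[[1]]$hr <- c(1, 1, 1)
  sim_n <- simulate_cohort(cfg_n)
  out_n <- simulate_outcomes(sim_n, cfg_n)
  tg <- sim_n$truth$prognostic$groups
  g <- tg$group[match(out_n$patient_id, tg$patient_id)]
  ps <- gray_test(out_n$time, out_n$event, g)$p
  expect_gt(ps, 0.001)
})

test_that("null configuration produces no downstream DMC calls", {
  cfg <- sim_config(n_cpg = 1500, n_per_subtype = c("HeH" = 12, "T-ALL" = 10),
                    n_reference = c(BM = 6, CD19 = 5, CD3 = 5, CD34 = 5),
                    n_relapse_pairs = 6, frac_constitutive = 0,
                    frac_subtype_unique = 0, frac_relapse = 0,
                    prognostic_regions = list(), n_corr_genes = 0, seed = 23)
  sim <- simulate_cohort(cfg)
  t1 <- call_dmcs(sim$beta, sim$sheet, "HeH")
  t2 <- call_dmcs(sim$beta, sim$sheet, "T-ALL")
  t3 <- call_relapse_dmcs(sim$beta, sim$sheet)
  expect_lte(sum(t1$is_dmc) + sum(t2$is_dmc) + sum(t3$is_dmc), 2)
})
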