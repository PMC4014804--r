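# Small cohort configurations shared across test files.

# two-subtype cohort with planted signals, small enough for fast DMC calls
small_cohort_config <- function(seed = 1L, n_cpg = 1200L) {
  sim_config(
    n_cpg = n_cpg,
    n_per_subtype = c("HeH" = 12, "T-ALL" = 10),
    n_reference = c(BM = 6, CD19 = 5, CD3 = 5, CD34 = 5),
    n_relapse_pairs = 20,
    frac_constitutive = 0.02,
    frac_subtype_unique = 0.01,
    frac_relapse = 0.015,
    n_corr_genes = 15,
    n_noise_genes = 40,
    seed = seed
  )
}

# single-stratum survival cohort: one subtype, n patients, one planted
# prognostic region with hazard ratio 5 for the hypomethylated group
survival_cohort_config <- function(seed = 1L, n_patients = 60L,
                                   n_cpg = 800L) {
  sim_config(
    n_cpg = n_cpg,
    n_per_subtype = c("t(12;21)" = n_patients),
    n_reference = c(BM = 5, CD19 = 5, CD3 = 0, CD34 = 5),
    n_relapse_pairs = 0,
    frac_constitutive = 0.01,
    frac_subtype_unique = 0.01,
    frac_relapse = 0,
    n_corr_genes = 10,
    n_noise_genes = 20,
    prognostic_regions = list(list(n_cpg = 4, hr = c(5, 1, 1))),
    seed = seed
  )
}

# brute-force two-sided rank-sum p by enumerating all group-A assignments
enum_ranksum_p <- function(a, b) {
  na <- length(a)
  vals <- c(a, b)
  r <- rank(vals)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(vals), na)
  stats <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- na * (length(vals) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# brute-force two-sided signed-rank p by enumerating all sign patterns
enum_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.vector(signs %*% r)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# brute-force BH step-up: q_(i) = min over j >= i of m * p_(j) / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- qs
  out
}

# brute-force one-sided hypergeometric tail: P(X >= a)
brute_hyper_tail <- function(a, class_size, bg_size, sig_size) {
  k <- a:min(class_size, sig_size)
  sum(exp(lchoose(class_size, k) + lchoose(bg_size - class_size, sig_size - k) -
            lchoose(bg_size, sig_size)))
}

# independently implemented K-sample log-rank chi-square
brute_logrank <- function(time, status, group) {
  groups <- sort(unique(group))
  K <- length(groups)
  evt <- sort(unique(time[status]))
  z <- numeric(K); V <- matrix(0, K, K)
  for (t in evt) {
    Y <- vapply(groups, function(g) sum(time >= t & group == g), numeric(1))
    d <- vapply(groups, function(g) sum(time == t & status & group == g),
                numeric(1))
    Yt <- sum(Y); dt <- sum(d)
    z <- z + d - Y * dt / Yt
    if (Yt > 1) {
      p <- Y / Yt
      V <- V + dt * (Yt - dt) / (Yt - 1) * (diag(p) - tcrossprod(p))
    }
  }
  zz <- z[-K]; VV <- V[-K, -K, drop = FALSE]
  as.numeric(t(zz) %*% solve(VV) %*% zz)
}
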