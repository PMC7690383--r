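# Shared fixture builders; everything is generated in code at test time.

# tiny deterministic beta matrix on the array scale
toy_beta <- function(n_probes = 6, n_samples = 4, seed = 42, scale = "array") {
  set.seed(seed)
  v <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes, n_samples,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (scale == "pyro") v <- v * 100
  beta_matrix(v, scale)
}

# marker-only cohort: a beta matrix with `p` probes whose first `n_informative`
# separate the classes by `delta` on within-group sd `sd`
two_class_beta <- function(n_pos = 11, n_neg = 21, p = 3, n_informative = p,
                           delta = 0.3, sd = 0.05, mu_neg = 0.3, seed = 1) {
  set.seed(seed)
  mu <- c(rep(mu_neg + delta, n_informative), rep(mu_neg, p - n_informative))
  pos <- matrix(rnorm(p * n_pos, mu, sd), p, n_pos)
  neg <- matrix(rnorm(p * n_neg, mu_neg, sd), p, n_neg)
  v <- pmin(pmax(cbind(pos, neg), 0.001), 0.999)
  dimnames(v) <- list(sprintf("cg%05d", seq_len(p)),
                      c(sprintf("pCR%02d", seq_len(n_pos)),
                        sprintf("pIR%02d", seq_len(n_neg))))
  list(beta = beta_matrix(v, "array"),
       samples = tibble::tibble(
         sample_id = colnames(v),
         group = rep(c("pCR", "pIR"), c(n_pos, n_neg))
       ))
}

# the configuration used for the scaled-down LOOCV replica: three markers at
# delta-beta 0.30 and within-group SD 0.05 among a small DM background
replica_config <- function(seed, n_probes = 300) {
  pcr <- c(0.55, 0.58, 0.52)
  mm <- cbind(NT = pcr, pCR = pcr, pIR = pcr - 0.30)
  sim_config(n_probes = n_probes, marker_means = mm, marker_sd = 0.05,
             seed = seed)
}

# independent step-up BH oracle: q_i = min_{j >= i} p_(j) * n / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- rev(q_sorted)
  q
}

# enumeration oracle for the two-sided Fisher exact p (point-probability rule)
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# enumeration oracle for the exact two-sided Mann-Whitney p
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  all_r <- seq_len(n1 + n2)
  u_all <- apply(combs, 2, function(idx) sum(all_r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
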