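# Independent oracles and small fixtures used across the suite.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  t <- table(a, b); n <- sum(t)
  si <- sum(choose(rowSums(t), 2)); sj <- sum(choose(colSums(t), 2))
  sij <- sum(choose(t, 2)); e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Brute-force two-sided Fisher p by explicit enumeration with choose(),
# independent of dhyper.
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  p_obs <- probs[m[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to group 1 (no ties assumed).
mw_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled_r <- rank(c(x, y))
  u_obs <- sum(pooled_r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(ix) sum(seq_len(nx + ny)[ix]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  # two-sided: assignments at least as far from the mean as observed
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Direct numerical maximization of the written-out Cox partial
# likelihood for a single covariate without ties (Breslow = Efron here).
cox_brute_oracle <- function(time, event, x) {
  negll <- function(b) {
    eta <- b * x
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s - (eta[i] - log(sum(exp(eta[risk]))))
    }
    s
  }
  stats::optimize(negll, c(-30, 30), tol = 1e-10)$minimum
}

# Small, fast generator configuration for unit tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_cohorts = 2, samples_per_cohort = c(60, 60), n_genes = 120,
             n_marker_genes = 30, seed = seed, ...)
}
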