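# Independent brute-force oracles used to validate the package's statistics.

# AUC by exhaustive pairwise comparison: P(score_pos > score_neg), ties 1/2.
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Exact two-sided Mann-Whitney p by enumerating all group-a position choices.
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  u_stat <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_stat(a, b)
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(u = u_obs, p = p)
}

# Grid-search least-squares T2 estimate: minimises the SSR of the
# monoexponential forward model over a dense (s0, t2) grid.
oracle_t2_grid <- function(signals, echo_times,
                           s0_range = c(500, 1500), t2_range = c(20, 400),
                           n_grid = 401) {
  s0s <- seq(s0_range[1], s0_range[2], length.out = n_grid)
  t2s <- seq(t2_range[1], t2_range[2], length.out = n_grid)
  best <- c(NA, NA, Inf)
  for (t2 in t2s) {
    decay <- exp(-echo_times / t2)
    # profile s0 analytically for each t2 (least squares in s0 is linear)
    s0_hat <- sum(signals * decay) / sum(decay^2)
    ssr <- sum((signals - s0_hat * decay)^2)
    if (ssr < best[3]) best <- c(s0_hat, t2, ssr)
  }
  list(s0 = best[1], t2 = best[2], ssr = best[3])
}
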