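# Independent oracles, coded from the definitions and kept separate from the
# package's computation paths.

# Benjamini-Hochberg step-up, literal formulation:
# sort ascending, q_i = min_{j>=i} min(1, m p_j / j), map back.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(1, m * ps / seq_len(m))
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments
# (requires distinct |d|, no zeros).
paired_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}

# Exact two-sided rank-sum p by enumeration of all C(m+n, m) group
# assignments (requires no ties in the pooled values).
unpaired_enum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(length(pooled), m)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Brute-force leave-one-out z-score: physically remove the focal value.
loo_z_brute <- function(values, i) {
  ref <- values[-i]
  (values[i] - mean(ref)) / stats::sd(ref)
}
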