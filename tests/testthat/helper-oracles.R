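# Independent oracles and small fixture builders used across tests.

# Benjamini-Hochberg step-up by explicit sort, independent of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Circular folding by the printed rule: min(|d| mod tau, tau - |d| mod tau).
fold_oracle <- function(d, tau = 24) {
  m <- abs(d) %% tau
  pmin(m, tau - m)
}

# One-sided hypergeometric tail by explicit enumeration.
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Standard 4-h two-condition design with r replicates.
make_design <- function(r = 4, conditions = c("NRF", "DRF"),
                        timepoints = c(2, 6, 10, 14, 18, 22)) {
  d <- expand.grid(
    replicate = seq_len(r), zt = timepoints, condition = conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("condition", "zt", "replicate")]
  d$sample_id <- sprintf("%s_ZT%02d_r%d", d$condition, d$zt, d$replicate)
  d$regime <- "LD"
  d[, c("sample_id", "zt", "condition", "replicate", "regime")]
}

# Signed wrap into (-tau/2, tau/2], independent of the package internals.
wrap_signed_oracle <- function(x, tau = 24) {
  w <- ((x %% tau) + tau) %% tau
  ifelse(w > tau / 2, w - tau, w)
}

# Cosinor evaluation used to build fixtures.
cosine_signal <- function(t, M, A, phi, tau = 24) {
  M + A * cos(2 * pi * (t - phi) / tau)
}
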