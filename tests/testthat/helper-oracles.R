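# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately naive and share no code with R/.

# O(m^2) Benjamini-Hochberg step-up: for each p_i, the adjusted value is the
# smallest m * p_j / rank_j over all p_j >= p_i, capped at 1, where rank_j
# counts how many p-values are <= p_j.
bh_brute <- function(p) {
  m <- length(p)
  rank_of <- vapply(p, function(pi) sum(p <= pi), numeric(1))
  vapply(seq_len(m), function(i) {
    candidates <- m * p[p >= p[i]] / rank_of[p >= p[i]]
    min(1, min(candidates))
  }, numeric(1))
}

# Windowed RMS fold-change std by explicit loops: rank by control reads
# descending (ties by id), take the window of N guides centred on each rank
# clamped at the edges, RMS about zero, optional running maximum.
eb_std_brute <- function(fc, control_norm, N, monotone = TRUE,
                         ids = seq_along(fc)) {
  n <- length(fc)
  ord <- order(-control_norm, ids)
  fs <- fc[ord]
  N <- min(N, n)
  half <- N %/% 2
  out_sorted <- numeric(n)
  for (j in seq_len(n)) {
    start <- min(max(j - half, 1), n - N + 1)
    out_sorted[j] <- sqrt(mean(fs[start:(start + N - 1)]^2))
  }
  if (monotone) out_sorted <- cummax(out_sorted)
  out <- numeric(n)
  out[ord] <- out_sorted
  out
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# size n_hits from the universe and count draws with >= k annotated members.
hyper_enum <- function(universe_size, n_annotated, n_hits, k) {
  if (n_hits == 0) return(1)
  draws <- utils::combn(universe_size, n_hits)
  annotated <- seq_len(n_annotated)
  mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
}

# Closed-form posterior mean of mu in the conjugate normal model where the
# prior precision on mu is tau_prior (independent of tau):
# E[mu | z] -> (tau_prior * mu_prior + n * ybar) / (tau_prior + n) in the
# weak-tau limit used throughout (see vignette).
ng_posterior_mean <- function(z, mu_prior = 0, tau_prior = 0.001) {
  n <- length(z)
  (tau_prior * mu_prior + n * mean(z)) / (tau_prior + n)
}

# Exact marginal posterior mean of mu for a single observation z under the
# semi-conjugate model, by numerical integration over tau:
# E[mu | tau, z] = (tau*z + tau_prior*mu_prior) / (tau + tau_prior) and
# p(tau | z) ~ Gamma(a, b) prior x N(z; mu_prior, 1/tau + 1/tau_prior)
# marginal likelihood.
ng_marginal_mean_single <- function(z, mu_prior = 0, tau_prior = 0.5,
                                    a_prior = 0.5, b_prior = 0.5) {
  w <- function(tau) {
    stats::dgamma(tau, a_prior, rate = b_prior) *
      stats::dnorm(z, mu_prior, sqrt(1 / tau + 1 / tau_prior))
  }
  num <- stats::integrate(function(tau) {
    w(tau) * (tau * z + tau_prior * mu_prior) / (tau + tau_prior)
  }, 0, Inf, rel.tol = 1e-10)$value
  den <- stats::integrate(w, 0, Inf, rel.tol = 1e-10)$value
  num / den
}

# Batch-means Monte-Carlo standard error of a chain's mean.
mcse_batch <- function(x, n_batches = 20) {
  m <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
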