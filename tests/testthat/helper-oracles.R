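# Independent oracles used to cross-check the analytic code paths.
# These deliberately use naive summation / exhaustive enumeration, not the
# survival functions the package calls.

# P(X >= x) for Binomial(n, p) by explicit term-by-term summation.
oracle_binom_tail <- function(x, n, p) {
  if (x > n) return(0)
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# Right tail of the hypergeometric overlap by exhaustive enumeration of all
# C(M, n) drawn sets, counting those overlapping the target set by >= x.
oracle_hyper_tail <- function(x, M, K, n) {
  if (n == 0L) return(if (x == 0L) 1 else 0)
  sets <- utils::combn(M, n)
  overlaps <- colSums(sets <= K)   # targets are taken as elements 1..K
  mean(overlaps >= x)
}

# Textbook BH step-up: sort, p(i) * m / i, cumulative min from the largest.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small null (no planted signal) configuration used by calibration tests.
null_config <- function(seed, n_genes = 200L, n_samples = 60L,
                        n_total_mutations = 1500L) {
  sim_config(seed = seed, n_genes = n_genes, n_samples = n_samples,
             amp_spec = NULL, del_spec = NULL, driver_spec = NULL,
             n_total_mutations = n_total_mutations,
             hpv_positive_fraction = 1)
}
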