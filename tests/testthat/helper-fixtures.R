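# Fixture builders shared across the suite. Everything is generated in code
# with explicit seeds; no data files.

# Homogeneous Poisson train times on [0, T] (independent of the package's
# thinning sampler, so it can serve as an oracle input).
poisson_times <- function(rate, T) sort(stats::runif(stats::rpois(1, rate * T), 0, T))

poisson_pair <- function(rate, T, seed) {
  withr::with_seed(seed, {
    t1 <- poisson_times(rate, T)
    t2 <- poisson_times(rate, T)
    spikes(c(t1, t2), rep(1:2, c(length(t1), length(t2))), 0, T,
           duplicates = "collapse")
  })
}

# O(n^2) brute-force correlogram oracle: enumerate every ordered pair and
# bin lags on the same half-open [-W, W) ms grid.
brute_force_cc <- function(tr, tt, window_ms = 50, bin_ms = 1, drop_self = FALSE) {
  lags <- as.vector(outer(tt, tr, "-")) * 1000
  if (drop_self) {
    # remove exactly one zero per self-pair (i = k), not coincident pairs
    self_lags <- rep(0, length(tr))
    for (l in self_lags) lags <- lags[-match(l, lags)]
  }
  lags <- lags[lags >= -window_ms & lags < window_ms]
  bins <- floor((lags + window_ms) / bin_ms) + 1
  tabulate(bins, 2 * window_ms / bin_ms)
}

# Correlogram object with given counts (for shape-model tests).
fake_correlogram <- function(counts, window_ms = 50, bin_ms = 1) {
  edges <- seq(-window_ms, window_ms, by = bin_ms)
  tibble::new_tibble(
    tibble::tibble(lag_left = edges[-length(edges)], lag_right = edges[-1],
                   count = as.integer(counts)),
    window_ms = window_ms, bin_ms = bin_ms, n_ref = 0L, n_tgt = 0L,
    duration = 1, ref = 1L, tgt = 2L, class = "correlogram"
  )
}
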