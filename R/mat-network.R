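#' Configure a MAT spiking-network simulation
#'
#' Default parameters describe a recurrent cortical-like network of 1,000
#' multi-timescale adaptive threshold (MAT) neurons: 800 excitatory cells
#' innervating 12.5% of other neurons with log-normally distributed
#' conductances, 200 inhibitory cells innervating 25% with normally
#' distributed conductances, conduction delays of a few ms, and per-neuron
#' Ornstein-Uhlenbeck background conductances standing in for the
#' unrecorded surrounding population. The global strength multiplier `A`
#' scales the whole connection matrix; raising it from 0.6 toward 1.8 drives
#' the network from asynchronous firing into synchronous bursting.
#'
#' @param n,n_exc Total and excitatory neuron counts.
#' @param p_exc,p_inh Connection probabilities by source type.
#' @param exc_log_mean,exc_log_sd Mean and SD of the natural log of
#'   excitatory conductances.
#' @param inh_mean,inh_sd Mean and SD of inhibitory conductances (negative
#'   draws are resampled).
#' @param A Strength multiplier applied once to the stored weight matrix.
#' @param delay_exc,delay_inh Uniform delay ranges (ms) by source type.
#' @param tau_m_exc,tau_m_inh Membrane time-constant ranges (ms), sampled
#'   uniformly per neuron.
#' @param VL,VE,VI Leak / excitatory / inhibitory reversal potentials (mV).
#' @param tau_se,tau_si Recurrent synaptic decay constants (ms).
#' @param tau1,tau2 Threshold decay timescales (ms).
#' @param omega_exc,omega_inh Resting thresholds (mV).
#' @param alpha1_exc_mean,alpha1_exc_sd Excitatory fast threshold jump:
#'   Gaussian mean and SD (mV).
#' @param alpha2_exc,alpha1_inh,alpha2_inh Remaining threshold jumps (mV).
#' @param tau_bge,tau_bgi,g0e,g0i,sig_e,sig_i Background OU conductance
#'   parameters (timescales in ms).
#' @param refractory_ms Absolute refractory period (ms); needed because the
#'   membrane potential is never reset.
#' @param dt Integration step (s).
#' @param duration Simulated time (s).
#' @return A list of class `mat_config`.
#' @export
mat_config <- function(n = 1000L, n_exc = 800L,
                       p_exc = 0.125, p_inh = 0.25,
                       exc_log_mean = -5.543, exc_log_sd = 1.30,
                       inh_mean = 0.0217, inh_sd = 0.00171,
                       A = 1,
                       delay_exc = c(3, 5), delay_inh = c(2, 4),
                       tau_m_exc = c(10, 20), tau_m_inh = c(5, 10),
                       VL = -70, VE = 0, VI = -80,
                       tau_se = 1, tau_si = 2,
                       tau1 = 10, tau2 = 200,
                       omega_exc = -56, omega_inh = -57,
                       alpha1_exc_mean = 10, alpha1_exc_sd = 0.3,
                       alpha2_exc = 1, alpha1_inh = 10, alpha2_inh = 0.2,
                       tau_bge = 2.7, tau_bgi = 10.5,
                       g0e = 1.85, g0i = 4.83,
                       sig_e = 0.245, sig_i = 0.400,
                       refractory_ms = 2,
                       dt = 1e-4, duration = 3600) {
  stopifnot(n_exc <= n, p_exc > 0, p_exc < 1, p_inh > 0, p_inh < 1,
            dt > 0, duration > 0)
  structure(as.list(environment()), class = "mat_config")
}

#' @export
print.mat_config <- function(x, ...) {
  cat(sprintf("<mat_config: %d neurons (%dE/%dI), A = %g, %g s at dt = %g s>\n",
              x$n, x$n_exc, x$n - x$n_exc, x$A, x$duration, x$dt))
  invisible(x)
}

#' Draw the random connectivity and per-neuron parameters
#'
#' Each ordered (source, target) pair with distinct neurons is connected
#' independently with the source type's probability. Excitatory conductances
#' are log-normal; inhibitory ones are normal with negative draws resampled,
#' so all weights are strictly positive (the sign is carried by the source
#' type). The strength multiplier `A` is applied once to the stored matrix;
#' the pre-multiplier weights are kept for ground-truth evaluation.
#'
#' @param config A [mat_config()] list.
#' @param seed Integer seed.
#' @return A list of class `mat_connectivity`: `weights` (A applied),
#'   `weights_base` (before A), `delays_ms`, `types` (`"exc"`/`"inh"` per
#'   neuron), `neurons` (per-neuron parameter tibble), `config`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mat_config"))
  withr::with_seed(as.integer(seed), {
    n <- config$n; n_exc <- config$n_exc
    types <- rep(c("exc", "inh"), c(n_exc, n - n_exc))
    W <- matrix(0, n, n)
    D <- matrix(0, n, n)
    for (j in seq_len(n)) {
      exc <- types[j] == "exc"
      p <- if (exc) config$p_exc else config$p_inh
      cand <- setdiff(seq_len(n), j)
      on <- cand[stats::runif(length(cand)) < p]
      if (!length(on)) next
      w <- if (exc) {
        exp(stats::rnorm(length(on), config$exc_log_mean, config$exc_log_sd))
      } else {
        draw_positive_normal(length(on), config$inh_mean, config$inh_sd)
      }
      rng <- if (exc) config$delay_exc else config$delay_inh
      W[j, on] <- w
      D[j, on] <- stats::runif(length(on), rng[1], rng[2])
    }
    neurons <- tibble::tibble(
      unit = seq_len(n),
      type = types,
      tau_m = ifelse(types == "exc",
                     stats::runif(n, config$tau_m_exc[1], config$tau_m_exc[2]),
                     stats::runif(n, config$tau_m_inh[1], config$tau_m_inh[2])),
      omega = ifelse(types == "exc", config$omega_exc, config$omega_inh),
      alpha1 = ifelse(types == "exc",
                      stats::rnorm(n, config$alpha1_exc_mean, config$alpha1_exc_sd),
                      config$alpha1_inh),
      alpha2 = ifelse(types == "exc", config$alpha2_exc, config$alpha2_inh)
    )
    structure(
      list(weights = W * config$A, weights_base = W, delays_ms = D,
           types = types, neurons = neurons, config = config),
      class = "mat_connectivity"
    )
  })
}

draw_positive_normal <- function(k, mean, sd) {
  w <- stats::rnorm(k, mean, sd)
  while (any(w <= 0)) {
    bad <- w <= 0
    w[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  w
}

#' @export
print.mat_connectivity <- function(x, ...) {
  cat(sprintf("<mat_connectivity: %d neurons, %d edges (%.1f%% density)>\n",
              length(x$types), sum(x$weights != 0),
              100 * mean(x$weights[!diag(nrow(x$weights)) == 1] != 0)))
  invisible(x)
}

#' Simulate the MAT network
#'
#' Integrates the network with the Euler-Maruyama scheme at the configured
#' step: leaky membrane without reset, conductance jumps delivered through a
#' per-target delay queue, a two-timescale adaptive threshold raised at each
#' spike, per-neuron OU background conductances (exact Gaussian transition,
#' clipped at zero), and a 2 ms absolute refractory period. Bitwise
#' reproducible for a given `(config, net, seed)`.
#'
#' @param config A [mat_config()] list.
#' @param net A [build_network()] result (or `NULL` to build one from
#'   `seed`).
#' @param seed Integer seed for the background noise (and network if built
#'   here).
#' @return A `spikes` data frame with units `1..n` over the configured
#'   duration.
#' @export
simulate_mat_network <- function(config, net = NULL, seed = 1L) {
  stopifnot(inherits(config, "mat_config"))
  if (is.null(net)) net <- build_network(config, seed = seed)
  res <- withr::with_seed(as.integer(seed) + 1L, {
    .mat_simulate(
      net$weights, net$delays_ms, as.integer(net$types == "exc"),
      net$neurons$tau_m, net$neurons$omega, net$neurons$alpha1, net$neurons$alpha2,
      config$VL, config$VE, config$VI,
      config$tau_se, config$tau_si, config$tau1, config$tau2,
      config$refractory_ms,
      config$tau_bge, config$tau_bgi, config$g0e, config$g0i,
      config$sig_e, config$sig_i,
      config$dt * 1000, config$duration
    )
  })
  sp <- tibble::tibble(time = res$time, unit = as.integer(res$unit))
  sp <- dplyr::arrange(sp, .data$unit, .data$time)
  new_spikes(sp, 0, config$duration)
}

#' Summarize the dynamical regime of a simulated population
#'
#' Bundles the population diagnostics used to tell the asynchronous regime
#' from synchronous bursting: population rate, the Fano factor of 10-ms
#' population spike counts (1 for Poisson-like asynchrony, large under
#' bursts), the cusp-versus-smooth comparison on the summed-train
#' auto-correlogram, and the dominant frequency of the population spectrum.
#'
#' @param x A non-empty `spikes` data frame.
#' @param fano_bin_s Bin for the population count series (s).
#' @return A one-row tibble: `pop_rate`, `fano`, `cusp_delta`,
#'   `cusp_preferred`, `peak_freq`.
#' @export
regime_summary <- function(x, fano_bin_s = 0.01) {
  x <- assert_spikes(x)
  if (!nrow(x)) stop("empty spike dataset", call. = FALSE)
  pooled <- sum_trains(x)
  h <- time_histogram(pooled, fano_bin_s)
  acg <- auto_correlogram(pooled, unit = 0L, include_self = FALSE)
  cusp <- cusp_vs_smooth_test(acg)
  ps <- power_spectrum(pooled, segment_s = min(10, floor(duration(x))))
  tibble::tibble(
    pop_rate = nrow(x) / duration(x),
    fano = stats::var(h$count) / mean(h$count),
    cusp_delta = cusp$delta,
    cusp_preferred = cusp$preferred,
    peak_freq = ps$frequency[which.max(ps$power)]
  )
}
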