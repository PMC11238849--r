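#' Specify a doubly stochastic rate model for a correlated pair
#'
#' Defines the shared instantaneous firing-rate process of a pair of neurons
#' that are *not* synaptically connected but are co-modulated by a common
#' input. These are the generative models whose cross-correlograms have
#' closed forms (see [analytic_cc()]):
#'
#' * `sinusoid`: `r1(t) = r1 + a1 sin(w t)`, `r2(t) = r2 + a2 sin(w t + phase)`;
#'   CC `r1 r2 + (a1 a2 / 2) cos(w t + phase)` — smooth undulation.
#' * `gabor`: as `sinusoid` but the oscillation frequency is redrawn each
#'   window from a normal law around `w` with SD `1/delta`, giving the damped
#'   (Gabor) CC `r1 r2 + (a1 a2 / 2) exp(-t^2 / (2 delta^2)) cos(w t + phase)`.
#' * `ou`: rate follows an Ornstein-Uhlenbeck process with mean `mu`,
#'   stationary SD `sigma` and relaxation rate `2 / tau_r`; continuous but
#'   nowhere differentiable, CC `mu^2 + sigma^2 exp(-2|t| / tau_r)` — a cusp.
#' * `telegraph`: Markov switching between `mu - sigma` and `mu + sigma`
#'   with exponential holding times of mean `tau_r`; identical CC to `ou`.
#' * `mixture`: weighted sum of component rate paths (no closed-form CC).
#'
#' @param variant One of `"sinusoid"`, `"gabor"`, `"ou"`, `"telegraph"`,
#'   `"mixture"`.
#' @param r1,r2 Base rates (spikes/s) for the oscillatory variants.
#' @param a1,a2 Oscillation amplitudes (spikes/s); need `r - |a| >= 0`.
#' @param freq_hz Oscillation frequency in Hz (stored as angular `omega`).
#' @param phase Phase lag of unit 2 (radians).
#' @param delta Frequency-spread scale of the Gabor variant (s): frequencies
#'   are drawn normally around `omega` with SD `1/delta`.
#' @param mu,sigma Mean and SD of the stochastic rate (spikes/s); need
#'   `mu - sigma >= 0` for `telegraph`.
#' @param tau_r Rate-fluctuation timescale (s).
#' @param lag Time by which unit 2's modulation lags behind unit 1's (s).
#' @param components,weights For `mixture`: list of `rate_model` specs and
#'   their weights.
#' @return A `rate_model` object.
#' @examples
#' rate_model("ou", mu = 20, sigma = 8, tau_r = 0.02)
#' @export
rate_model <- function(variant = c("sinusoid", "gabor", "ou", "telegraph", "mixture"),
                       r1 = 20, r2 = r1, a1 = 0, a2 = a1, freq_hz = 5,
                       phase = 0, delta = 0.1,
                       mu = 20, sigma = 0, tau_r = 0.02, lag = 0,
                       components = NULL, weights = NULL) {
  variant <- match.arg(variant)
  if (variant %in% c("sinusoid", "gabor")) {
    if (r1 - abs(a1) < 0 || r2 - abs(a2) < 0) {
      stop("need r - |a| >= 0 so the instantaneous rate stays non-negative", call. = FALSE)
    }
  }
  if (variant == "telegraph" && mu - sigma < 0) {
    stop("telegraph rates mu - sigma and mu + sigma must be non-negative", call. = FALSE)
  }
  if (variant %in% c("ou", "telegraph") && tau_r <= 0) {
    stop("`tau_r` must be positive", call. = FALSE)
  }
  if (variant == "mixture") {
    if (is.null(components) || !length(components)) {
      stop("mixture needs a list of component `rate_model` specs", call. = FALSE)
    }
    weights <- weights %||% rep(1, length(components))
    if (length(weights) != length(components)) {
      stop("`weights` must match `components` in length", call. = FALSE)
    }
  }
  structure(
    list(variant = variant, r1 = r1, r2 = r2, a1 = a1, a2 = a2,
         omega = 2 * pi * freq_hz, phase = phase, delta = delta,
         mu = mu, sigma = sigma, tau_r = tau_r, lag = lag,
         components = components, weights = weights),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model:", x$variant, ">\n")
  invisible(x)
}

check_dt <- function(spec, dt) {
  if (dt > spec_tau_min(spec) / 10) {
    stop("`dt` too coarse for the rate timescale; need dt <= tau_r / 10", call. = FALSE)
  }
}

spec_tau_min <- function(spec) {
  if (spec$variant == "mixture") {
    min(vapply(spec$components, spec_tau_min, 0))
  } else if (spec$variant %in% c("ou", "telegraph")) spec$tau_r else Inf
}

# Both units' raw (unclipped) rate paths on `grid`, drawn from the *current*
# RNG state. Stochastic variants draw one shared realization and slice it so
# that unit2(t) = unit1(t - lag).
pair_paths <- function(spec, grid) {
  dt <- grid[2] - grid[1]
  lag <- spec$lag
  switch(spec$variant,
    sinusoid = list(
      r1 = spec$r1 + spec$a1 * sin(spec$omega * grid),
      r2 = spec$r2 + spec$a2 * sin(spec$omega * (grid - lag) + spec$phase)
    ),
    gabor = {
      om <- gabor_omegas(spec, grid)
      list(
        r1 = spec$r1 + spec$a1 * sin(om * grid),
        r2 = spec$r2 + spec$a2 * sin(om * (grid - lag) + spec$phase)
      )
    },
    ou = {
      n_pre <- as.integer(round(abs(lag) / dt))
      shared <- ou_path_raw(length(grid) + n_pre, dt, spec$mu, spec$sigma, spec$tau_r)
      lead <- shared[n_pre + seq_along(grid)] # later window = leading unit
      trail <- shared[seq_along(grid)]
      if (lag >= 0) list(r1 = lead, r2 = trail) else list(r1 = trail, r2 = lead)
    },
    telegraph = {
      t_max <- max(grid) + abs(lag) + 10 * spec$tau_r
      sw <- telegraph_draw(t_max, spec$tau_r)
      lead <- telegraph_eval(sw, grid + abs(lag), spec$mu, spec$sigma)
      trail <- telegraph_eval(sw, grid, spec$mu, spec$sigma)
      if (lag >= 0) list(r1 = lead, r2 = trail) else list(r1 = trail, r2 = lead)
    },
    mixture = {
      parts <- Map(function(s, w) {
        p <- pair_paths(s, grid)
        list(r1 = w * p$r1, r2 = w * p$r2)
      }, spec$components, spec$weights)
      list(
        r1 = Reduce(`+`, lapply(parts, `[[`, "r1")),
        r2 = Reduce(`+`, lapply(parts, `[[`, "r2"))
      )
    }
  )
}

# Frequencies redrawn per 10-s window: normal around omega with SD 1/delta.
gabor_omegas <- function(spec, grid, window_s = 10) {
  idx <- floor(grid / window_s) + 1L
  draws <- stats::rnorm(max(idx), spec$omega, 1 / spec$delta)
  draws[idx]
}

# Exact Gaussian transition of the OU process with relaxation rate 2/tau_r
# and stationary SD sigma, initialized from the stationary law. The
# stationary autocovariance sigma^2 exp(-2|t|/tau_r) is the contract.
ou_path_raw <- function(n, dt, mu, sigma, tau_r) {
  e1 <- exp(-2 * dt / tau_r)
  z <- stats::rnorm(n)
  r0 <- sigma * z[1]
  if (n == 1) return(mu + r0)
  innov <- sigma * sqrt(1 - e1^2) * z[-1]
  dev <- stats::filter(innov, e1, method = "recursive", init = r0)
  mu + c(r0, as.numeric(dev))
}

telegraph_draw <- function(t_max, tau_r) {
  n_guess <- as.integer(ceiling(t_max / tau_r + 10 * sqrt(t_max / tau_r) + 10))
  holds <- stats::rexp(n_guess, rate = 1 / tau_r)
  while (sum(holds) < t_max) holds <- c(holds, stats::rexp(n_guess, rate = 1 / tau_r))
  list(times = cumsum(holds), state0 = stats::rbinom(1, 1, 0.5))
}

telegraph_eval <- function(sw, tt, mu, sigma) {
  k <- findInterval(tt, sw$times)
  mu + sigma * (2 * ((sw$state0 + k) %% 2) - 1)
}

#' Sample a realization of the rate process
#'
#' @param spec A [rate_model()] specification.
#' @param duration Length of the path (s).
#' @param dt Time step (s); for stochastic variants `dt <= tau_r / 10` is
#'   enforced.
#' @param seed Integer seed.
#' @param unit Which unit's path (1 or 2): unit 2 carries the phase/time lag.
#' @return A tibble with `time` (s) and `rate` (spikes/s, clipped at 0).
#' @export
sample_rate_path <- function(spec, duration, dt, seed, unit = 1L) {
  check_dt(spec, dt)
  grid <- seq(0, duration, by = dt)
  p <- withr::with_seed(as.integer(seed), pair_paths(spec, grid))
  r <- if (unit == 1L) p$r1 else p$r2
  tibble::tibble(time = as.numeric(grid), rate = pmax(r, 0))
}

#' Sample an inhomogeneous Poisson spike train from a rate path
#'
#' Thinning against the path maximum: homogeneous candidates at the peak rate
#' are kept with probability `r(t) / r_max` (rate linearly interpolated
#' between grid points). The expected spike count is the integral of the
#' rate.
#'
#' @param path A tibble with `time` and `rate` as from [sample_rate_path()].
#' @param seed Integer seed.
#' @param unit Unit id for the output train.
#' @return A `spikes` data frame spanning the path.
#' @export
sample_inhomogeneous_poisson <- function(path, seed, unit = 1L) {
  if (any(path$rate < 0)) stop("rate path must be non-negative", call. = FALSE)
  t0 <- min(path$time); t1 <- max(path$time)
  withr::with_seed(as.integer(seed), {
    tm <- thin_poisson(path, t0, t1, max(path$rate))
    spikes(tm, unit, t_start = t0, t_stop = t1, duplicates = "collapse")
  })
}

thin_poisson <- function(path, t0, t1, rmax) {
  if (rmax <= 0) return(numeric(0))
  n_prop <- stats::rpois(1, rmax * (t1 - t0))
  if (n_prop == 0) return(numeric(0))
  tp <- sort(stats::runif(n_prop, t0, t1))
  r_at <- stats::approx(path$time, path$rate, xout = tp, rule = 2)$y
  tp[stats::runif(n_prop) < r_at / rmax]
}

#' Generate a co-modulated, unconnected spike-train pair
#'
#' Draws one realization of the shared rate process and then two
#' conditionally independent Poisson trains from it (unit 2 with the spec's
#' phase or time lag applied). No spike of one train influences the other:
#' any correlogram structure reflects the common input only, which is exactly
#' the null situation in which naive correlogram tests report spurious
#' connections.
#'
#' @inheritParams sample_rate_path
#' @return A `spikes` data frame with units `1` and `2`.
#' @export
generate_pair <- function(spec, duration, dt = 0.002, seed = 1L) {
  check_dt(spec, dt)
  withr::with_seed(as.integer(seed), {
    grid <- seq(0, duration, by = dt)
    p <- pair_paths(spec, grid)
    r1 <- pmax(p$r1, 0); r2 <- pmax(p$r2, 0)
    t1 <- thin_poisson(tibble::tibble(time = as.numeric(grid), rate = r1), 0, duration, max(r1))
    t2 <- thin_poisson(tibble::tibble(time = as.numeric(grid), rate = r2), 0, duration, max(r2))
    spikes(c(t1, t2), rep(c(1L, 2L), c(length(t1), length(t2))),
           t_start = 0, t_stop = duration, duplicates = "collapse")
  })
}

#' Closed-form cross-correlogram of a rate-model pair
#'
#' Evaluates the analytic pair-rate density (spikes^2/s^2) of the spec's
#' variant at the requested lags:
#' sinusoid `r1 r2 + (a1 a2/2) cos(w t + phase)`; gabor the same damped by
#' `exp(-t^2/(2 delta^2))`; `ou` and `telegraph` both
#' `mu^2 + sigma^2 exp(-2|t|/tau_r)`.
#'
#' @param spec A [rate_model()] specification (not `mixture`).
#' @param lags_ms Numeric vector of lags in ms.
#' @return A tibble with `lag_ms` and `cc` (spikes^2/s^2).
#' @export
analytic_cc <- function(spec, lags_ms) {
  t <- lags_ms / 1000
  cc <- switch(spec$variant,
    sinusoid = spec$r1 * spec$r2 +
      spec$a1 * spec$a2 / 2 * cos(spec$omega * t + spec$phase),
    gabor = spec$r1 * spec$r2 +
      spec$a1 * spec$a2 / 2 * exp(-t^2 / (2 * spec$delta^2)) *
        cos(spec$omega * t + spec$phase),
    ou = ,
    telegraph = spec$mu^2 + spec$sigma^2 * exp(-2 * abs(t) / spec$tau_r),
    stop("no closed-form correlogram for variant `", spec$variant, "`", call. = FALSE)
  )
  tibble::tibble(lag_ms = lags_ms, cc = cc)
}

#' Generate a pair with a known injected monosynaptic connection
#'
#' The generative twin of the GLM observation model, used for recovery
#' benchmarks. The presynaptic train is Poisson with rate `r_pre` (or the
#' shared `background` path); the postsynaptic intensity is
#' `r_post(t) * exp(J * sum_k f(t - t_k))` with `f` the delayed exponential
#' synaptic kernel of [synaptic_kernel()] and `t_k` the presynaptic spikes,
#' so `J` is exactly the coupling the GLM estimators try to recover.
#'
#' @param r_pre,r_post Base rates (spikes/s).
#' @param J Dimensionless coupling (positive excitatory, negative inhibitory).
#' @param tau_s Synaptic timescale (ms).
#' @param d Transmission delay (ms).
#' @param duration Recording length (s).
#' @param background Optional [rate_model()] spec; if given, both units share
#'   its rate path (scaled to their base rates) in place of constant rates.
#' @param seed Integer seed.
#' @param max_gain Safety cap on `exp(J * f_sum)`; exceeding it raises an
#'   error suggesting a smaller `J`.
#' @return A list with `spikes` (units 1 = pre, 2 = post) and `truth`, a
#'   one-row tibble `(pre, post, J, tau_s, d)`.
#' @export
inject_synaptic_pair <- function(r_pre, r_post, J, tau_s = 2, d = 2, duration = 3600,
                                 background = NULL, seed = 1L, max_gain = exp(8)) {
  tau_s_s <- tau_s / 1000
  d_s <- d / 1000
  withr::with_seed(as.integer(seed), {
    if (is.null(background)) {
      pre_path <- tibble::tibble(time = c(0, duration), rate = r_pre)
      post_base <- tibble::tibble(time = c(0, duration), rate = r_post)
    } else {
      dt <- max(min(spec_tau_min(background) / 10, 0.01), 1e-4)
      grid <- seq(0, duration, by = dt)
      raw <- pmax(pair_paths(background, grid)$r1, 0)
      m <- mean(raw)
      pre_path <- tibble::tibble(time = as.numeric(grid), rate = raw * (r_pre / m))
      post_base <- tibble::tibble(time = as.numeric(grid), rate = raw * (r_post / m))
    }
    t_pre <- thin_poisson(pre_path, 0, duration, max(pre_path$rate))

    # Running kernel sum S at each delivery time (pre spike + delay),
    # including that delivery's own unit contribution.
    ev <- t_pre + d_s
    S <- kernel_sum_at_events(ev, tau_s_s)
    gain_max <- exp(max(J, 0) * max(S, 0))
    if (gain_max > max_gain) {
      stop("postsynaptic intensity cap exceeded; use a smaller J", call. = FALSE)
    }
    lam_max <- max(post_base$rate) * gain_max
    n_prop <- stats::rpois(1, lam_max * duration)
    tp <- sort(stats::runif(n_prop, 0, duration))
    i <- findInterval(tp, ev)
    fsum <- ifelse(i > 0, S[pmax(i, 1)] * exp(-(tp - ev[pmax(i, 1)]) / tau_s_s), 0)
    base <- stats::approx(post_base$time, post_base$rate, xout = tp, rule = 2)$y
    lam <- base * exp(J * fsum)
    t_post <- tp[stats::runif(n_prop) < lam / lam_max]

    sp <- spikes(c(t_pre, t_post), rep(c(1L, 2L), c(length(t_pre), length(t_post))),
                 t_start = 0, t_stop = duration, duplicates = "collapse")
    list(
      spikes = sp,
      truth = tibble::tibble(pre = 1L, post = 2L, J = J, tau_s = tau_s, d = d)
    )
  })
}

kernel_sum_at_events <- function(ev, tau_s_s) {
  n <- length(ev)
  if (!n) return(numeric(0))
  S <- numeric(n)
  S[1] <- 1
  if (n > 1) {
    decay <- exp(-diff(ev) / tau_s_s)
    for (k in 2:n) S[k] <- S[k - 1] * decay[k - 1] + 1
  }
  S
}
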