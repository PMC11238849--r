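test_that("rate paths honor their defining constraints", {
  tel <- rate_model("telegraph", mu = 20, sigma = 8, tau_r = 0.05)
  p <- sample_rate_path(tel, 20, 0.005, seed = 2)
  expect_true(all(p$rate %in% c(12, 28)))
  expect_true(any(p$rate == 12) && any(p$rate == 28))

  sinu <- rate_model("sinusoid", r1 = 20, a1 = 10, freq_hz = 5)
  p2 <- sample_rate_path(sinu, 1, 0.001, seed = 1)
  expect_equal(p2$rate[1], 20)   # sin(0) = 0

  expect_error(sample_rate_path(rate_model("ou", mu = 10, sigma = 2, tau_r = 0.02),
                                10, 0.01, seed = 1), "dt")
  expect_error(rate_model("telegraph", mu = 5, sigma = 9), "non-negative")
  expect_error(rate_model("sinusoid", r1 = 5, a1 = 9), "non-negative")
})

test_that("the OU rate has stationary mean mu and SD sigma", {
  spec <- rate_model("ou", mu = 20, sigma = 5, tau_r = 0.02)
  p <- sample_rate_path(spec, 3600, 0.002, seed = 14)
  # SE of the mean for an OU path: sigma * sqrt(tau_r / T)
  se <- 5 * sqrt(0.02 / 3600)
  expect_lt(abs(mean(p$rate) - 20), 3 * se)
  expect_lt(abs(stats::sd(p$rate) - 5) / 5, 0.05)
})

test_that("closed-form correlograms match their printed formulas", {
  sinu <- rate_model("sinusoid", r1 = 20, r2 = 15, a1 = 10, a2 = 6,
                     freq_hz = 5, phase = 0)
  expect_equal(analytic_cc(sinu, 0)$cc, 20 * 15 + 10 * 6 / 2)
  # quarter period of 5 Hz = 50 ms: cos term vanishes
  expect_equal(analytic_cc(sinu, 50)$cc, 300, tolerance = 1e-12)

  ou <- rate_model("ou", mu = 20, sigma = 8, tau_r = 0.02)
  expect_equal(analytic_cc(ou, 0)$cc, 400 + 64)
  expect_equal(analytic_cc(ou, 1e6)$cc, 400)   # exponential term vanishes
  tel <- rate_model("telegraph", mu = 20, sigma = 8, tau_r = 0.02)
  lags <- seq(-50, 50, by = 0.5)
  expect_equal(analytic_cc(tel, lags)$cc, analytic_cc(ou, lags)$cc)

  gab <- rate_model("gabor", r1 = 20, a1 = 10, freq_hz = 5, delta = 0.05)
  expect_equal(analytic_cc(gab, 0)$cc, 450)
  t40 <- 0.04
  expect_equal(analytic_cc(gab, 40)$cc,
               400 + 50 * exp(-t40^2 / (2 * 0.05^2)) * cos(2 * pi * 5 * t40))
  # the Gaussian envelope damps the undulation relative to the pure sinusoid
  expect_lt(abs(analytic_cc(gab, 40)$cc - 400), abs(50 * cos(2 * pi * 5 * t40)))

  mix <- rate_model("mixture", components = list(sinu, ou))
  expect_error(analytic_cc(mix, 0), "closed-form")
})

test_that("inhomogeneous Poisson sampling has the right mass and linearity", {
  zero <- tibble::tibble(time = c(0, 10), rate = 0)
  expect_equal(nrow(sample_inhomogeneous_poisson(zero, seed = 1)), 0L)

  const <- tibble::tibble(time = c(0, 1000), rate = 10)
  n1 <- nrow(sample_inhomogeneous_poisson(const, seed = 2))
  expect_lt(abs(n1 - 10000), 4 * sqrt(10000))

  dbl <- tibble::tibble(time = c(0, 1000), rate = 20)
  n2 <- nrow(sample_inhomogeneous_poisson(dbl, seed = 3))
  expect_lt(abs(n2 - 2 * n1), 4 * sqrt(2 * 20000))
})

test_that("generated pairs reproduce their analytic correlograms", {
  # zero-amplitude spec: two independent homogeneous trains, flat CC
  flat <- generate_pair(rate_model("sinusoid", r1 = 15, a1 = 0), 1200, seed = 5)
  cc <- cross_correlogram(flat, 1, 2)
  expected <- 15 * 15 * 1200 * 0.001
  expect_true(all(abs(cc$count - expected) < 4.5 * sqrt(expected)))

  # OU cusp: zero-lag bins exceed the far tail
  ou <- rate_model("ou", mu = 20, sigma = 10, tau_r = 0.02)
  ccu <- cross_correlogram(generate_pair(ou, 3600, seed = 6), 1, 2)
  ctr <- (ccu$lag_left + ccu$lag_right) / 2
  expect_gt(mean(ccu$count[abs(ctr) <= 1]),
            mean(ccu$count[abs(ctr) >= 40]) + 3 * sqrt(mean(ccu$count[abs(ctr) >= 40])))

  # lagged oscillation: template matching recovers the imposed lag to 1 bin
  lagged <- rate_model("sinusoid", r1 = 40, a1 = 30, freq_hz = 5, lag = 0.012)
  ccl <- cross_correlogram(generate_pair(lagged, 1800, seed = 7), 1, 2)
  template <- function(shift_ms) {
    pred <- analytic_cc(rate_model("sinusoid", r1 = 40, a1 = 30, freq_hz = 5),
                        ctr - shift_ms)$cc * 1800 * 0.001
    sum((ccl$count - pred)^2)
  }
  shifts <- seq(-25, 25, by = 1)
  best <- shifts[which.min(vapply(shifts, template, 0))]
  expect_lte(abs(best - 12), 1)
})

test_that("empirical correlograms of all variants pass a chi-square test against theory", {
  # Pearson X^2 over the 100 bins vs the analytic pair-rate density,
  # evaluated bin-wise by exact integration (here: midpoint suffices for
  # the cusp; the oscillation uses the exact integral of cos).
  check_variant <- function(spec, duration, seed) {
    cc <- cross_correlogram(generate_pair(spec, duration, seed = seed), 1, 2)
    ctr <- (cc$lag_left + cc$lag_right) / 2
    expected <- analytic_cc(spec, ctr)$cc * duration * 0.001
    x2 <- sum((cc$count - expected)^2 / expected)
    expect_lt(x2, stats::qchisq(0.99, df = length(expected)))
  }
  check_variant(rate_model("telegraph", mu = 20, sigma = 8, tau_r = 0.02), 1800, 31)
  check_variant(rate_model("gabor", r1 = 20, a1 = 10, freq_hz = 5, delta = 0.05),
                1800, 32)
})

test_that("OU and telegraph pairs with matched moments are indistinguishable", {
  ou <- generate_pair(rate_model("ou", mu = 20, sigma = 8, tau_r = 0.02),
                      1800, seed = 41)
  tel <- generate_pair(rate_model("telegraph", mu = 20, sigma = 8, tau_r = 0.02),
                       1800, seed = 42)
  c1 <- cross_correlogram(ou, 1, 2)$count
  c2 <- cross_correlogram(tel, 1, 2)$count
  # two-sample homogeneity chi-square across bins
  x2 <- sum((c1 - c2)^2 / (c1 + c2))
  expect_lt(x2, stats::qchisq(0.995, df = 100))
})

test_that("injected synaptic pairs carry the coupling where the kernel lives", {
  null <- inject_synaptic_pair(8, 8, J = 0, duration = 1200, seed = 51)
  ccn <- cross_correlogram(null$spikes, 1, 2)
  expected <- 8 * 8 * 1200 * 0.001
  expect_true(all(abs(ccn$count - expected) < 4.5 * sqrt(expected)))
  expect_equal(null$truth$J, 0)

  exc <- inject_synaptic_pair(8, 8, J = 1, tau_s = 2, d = 2, duration = 1800, seed = 52)
  cce <- cross_correlogram(exc$spikes, 1, 2)
  ctr <- (cce$lag_left + cce$lag_right) / 2
  base <- mean(cce$count[ctr < 0])
  win <- ctr >= 2 & ctr <= 10
  expect_gt(mean(cce$count[win]), base + 4 * sqrt(base / sum(win)))

  inh <- inject_synaptic_pair(8, 8, J = -2, tau_s = 2, d = 2, duration = 1800, seed = 53)
  cci <- cross_correlogram(inh$spikes, 1, 2)
  expect_lt(mean(cci$count[win]), base)

  expect_error(inject_synaptic_pair(50, 5, J = 12, duration = 10, seed = 1),
               "smaller J")
})
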