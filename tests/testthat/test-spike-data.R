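test_that("reading two-column spike text parses units, spans and dialects", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.001 0", "0.002 1", "0.003 0"), p)
  ds <- read_spike_trains(p)
  expect_equal(sort(unique(ds$unit)), c(0L, 1L))
  expect_equal(unit_times(ds, 0), c(0.001, 0.003))
  expect_equal(unit_times(ds, 1), 0.002)
  expect_equal(t_start(ds), 0)

  # comma dialect with a header
  writeLines(c("time_s,unit_id", "0.5,3", "1.25,4"), p)
  ds2 <- read_spike_trains(p)
  expect_equal(sort(unique(ds2$unit)), c(3L, 4L))
  expect_equal(unit_times(ds2, 4), 1.25)

  # malformed row names its line
  writeLines(c("0.001 0", "abc 0", "0.003 1"), p)
  expect_error(read_spike_trains(p), "line 2")

  # explicit span violations are rejected
  writeLines(c("0.5 1", "9.5 1"), p)
  expect_error(read_spike_trains(p, span = c(0, 5)), "span")
  ds3 <- read_spike_trains(p, span = c(0, 10))
  expect_equal(t_stop(ds3), 10)
})

test_that("write/read round trip is the identity", {
  p <- withr::local_tempfile(fileext = ".txt")
  sp <- poisson_pair(20, 30, seed = 5)
  write_spike_trains(sp, p)
  back <- read_spike_trains(p, span = c(t_start(sp), t_stop(sp)))
  expect_equal(back$unit, sp$unit)
  expect_equal(back$time, sp$time, tolerance = 1e-9)
})

test_that("duplicate timestamps within a unit are rejected unless collapsed", {
  expect_error(spikes(c(0.1, 0.1), c(1L, 1L)), "duplicate")
  sp <- spikes(c(0.1, 0.1, 0.1), c(1L, 1L, 2L), duplicates = "collapse")
  expect_equal(nrow(sp), 2L)
  # coincident spikes of different units are fine
  expect_silent(spikes(c(0.1, 0.1), c(1L, 2L)))
})

test_that("sum_trains merges sorted and conserves the spike count", {
  one <- spikes(c(0.1, 0.3), 7L, t_stop = 1)
  s1 <- sum_trains(one)
  expect_equal(s1$time, c(0.1, 0.3))
  expect_equal(unique(s1$unit), 0L)

  two <- spikes(c(0.1, 0.3, 0.2), c(1L, 1L, 2L), t_stop = 1)
  expect_equal(sum_trains(two)$time, c(0.1, 0.2, 0.3))

  big <- withr::with_seed(3, {
    times <- lapply(1:50, function(u) poisson_times(4, 60))
    spikes(unlist(times), rep(1:50, lengths(times)), 0, 60, duplicates = "collapse")
  })
  expect_equal(nrow(sum_trains(big)), nrow(big))
  expect_error(sum_trains(spikes(numeric(0), integer(0), 0, 1)), "empty")
})

test_that("time_histogram conserves counts and matches the Poisson mean", {
  sp <- spikes(c(0.1, 0.2, 0.3, 0.4, 0.5), 1L, 0, 1)
  expect_equal(time_histogram(sp, 1)$count, 5L)
  sp2 <- spikes(c(0.005, 0.015), 1L, 0, 0.02)
  expect_equal(time_histogram(sp2, 0.01)$count, c(1L, 1L))
  expect_error(time_histogram(sp, -1), "positive")

  # homogeneous Poisson at 100/s, 100 s, 10-ms bins: mean count ~ 1
  h <- withr::with_seed(11, {
    tt <- poisson_times(100, 100)
    time_histogram(spikes(tt, 1L, 0, 100, duplicates = "collapse"), 0.01)
  })
  expect_equal(sum(h$count), length(withr::with_seed(11, poisson_times(100, 100))))
  se <- stats::sd(h$count) / sqrt(nrow(h))
  expect_lt(abs(mean(h$count) - 1), 3 * se)
})

test_that("jitter surrogate preserves counts, respects the span, vanishes at tiny width", {
  sp <- poisson_pair(10, 20, seed = 8)
  j <- jitter_surrogate(sp, half_width = 0.005, seed = 1)
  expect_equal(nrow(j), nrow(sp))
  expect_equal(table(j$unit), table(sp$unit))
  expect_true(all(j$time >= t_start(sp) & j$time <= t_stop(sp)))
  expect_identical(jitter_surrogate(sp, 0.005, seed = 4),
                   jitter_surrogate(sp, 0.005, seed = 4))
  tiny <- jitter_surrogate(sp, 1e-12, seed = 2)
  expect_equal(tiny$time, sp$time, tolerance = 1e-9)
  expect_error(jitter_surrogate(sp, 0, seed = 1), "half_width")
})

test_that("a 2-ms dither flattens a correlogram cusp by the triangular-smear factor", {
  # Derivation: jittering both trains by U(-2, 2) ms convolves the lag axis
  # with a triangular kernel on (-4, 4) ms. For a cusp sigma^2 exp(-2|t|/tau_r)
  # the expected ratio of the central (+-1 ms) excess over the 5-10 ms
  # baseline, after vs before, is the convolution integral below.
  tau_ms <- 1
  cusp_fun <- function(t) exp(-2 * abs(t) / tau_ms)
  tri <- function(e) ifelse(abs(e) < 4, (4 - abs(e)) / 16, 0)
  smear <- function(t) stats::integrate(function(e) tri(e) * cusp_fun(t - e), -4, 4)$value
  excess <- function(f) {
    ctr <- stats::integrate(Vectorize(f), 0, 1)$value
    base <- stats::integrate(Vectorize(f), 5, 10)$value / 5
    ctr - base
  }
  ratio_pred <- excess(smear) / excess(cusp_fun)

  spec <- rate_model("ou", mu = 200, sigma = 100, tau_r = tau_ms / 1000)
  sp <- generate_pair(spec, duration = 900, dt = 1e-4, seed = 21)
  jit <- function(x) {
    u1 <- jitter_surrogate(spikes(unit_times(x, 1), 1L, 0, duration(x),
                                  duplicates = "collapse"), 0.002, seed = 31)
    u2 <- jitter_surrogate(spikes(unit_times(x, 2), 2L, 0, duration(x),
                                  duplicates = "collapse"), 0.002, seed = 32)
    spikes(c(u1$time, u2$time), c(u1$unit, u2$unit), 0, duration(x),
           duplicates = "collapse")
  }
  meas <- function(x) {
    cc <- cross_correlogram(x, 1, 2)
    ctr <- (cc$lag_left + cc$lag_right) / 2
    mean(cc$count[abs(ctr) <= 1]) - mean(cc$count[abs(ctr) >= 5 & abs(ctr) <= 10])
  }
  before <- meas(sp)
  after <- meas(jit(sp))
  expect_gt(before, 0)
  expect_lt(after / before, 0.75)                     # the cusp flattens
  expect_lt(abs(after / before - ratio_pred), 0.2)    # by about the predicted factor
})

test_that("ISI shuffle preserves per-unit interval multisets and kills co-bursting", {
  sp <- poisson_pair(10, 30, seed = 9)
  sh <- shuffle_surrogate(sp, seed = 3)
  for (u in 1:2) {
    expect_equal(sort(diff(unit_times(sh, u))), sort(diff(unit_times(sp, u))),
                 tolerance = 1e-9)
  }
  two <- spikes(c(0.1, 0.4), 1L, 0, 1)
  sh2 <- shuffle_surrogate(two, seed = 1)
  expect_equal(sort(sh2$time), c(0.1, 0.4))

  # co-bursting units (shared telegraph rate): population Fano factor drops
  bursty <- withr::with_seed(17, {
    spec <- rate_model("telegraph", mu = 10, sigma = 9, tau_r = 0.1)
    path <- sample_rate_path(spec, 120, 0.01, seed = 55)
    parts <- lapply(1:20, function(u) {
      unit_times_u <- sample_inhomogeneous_poisson(path, seed = 100 + u, unit = u)
      unit_times_u$time
    })
    spikes(unlist(parts), rep(1:20, lengths(parts)), 0, 120, duplicates = "collapse")
  })
  fano <- function(x) {
    h <- time_histogram(sum_trains(x), 0.05)
    stats::var(h$count) / mean(h$count)
  }
  expect_gt(fano(bursty), 2)
  expect_lt(fano(shuffle_surrogate(bursty, seed = 6)), fano(bursty) / 2)
})
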