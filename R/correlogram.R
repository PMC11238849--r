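#' Cross-correlogram of two spike trains
#'
#' Counts every ordered spike pair `(t_ref, t_tgt)` of the reference and
#' target trains whose lag `t_tgt - t_ref` falls within the window, binned on
#' a half-open millisecond grid. A positive lag means the target fires after
#' the reference; for a pair of independent trains the correlogram is flat at
#' `r_ref * r_tgt * T * bin` counts per bin, and deviations from flatness are
#' the raw material of every connectivity test in this package.
#'
#' Bins are half-open `[k, k+1)` ms with zero lag belonging to the `[0, 1)`
#' bin, so the countable window is `[-W, +W)`. Spikes near the recording edge
#' are still used as references (plain superposition; no edge correction).
#'
#' @param x A `spikes` data frame containing both units.
#' @param ref,tgt Unit ids of the reference and target trains.
#' @param window_ms Half-window W in ms (default 50).
#' @param bin_ms Bin width in ms (default 1); W must be a multiple of it.
#' @return A tibble of class `correlogram` with columns `lag_left`,
#'   `lag_right` (ms) and `count`, and attributes `window_ms`, `bin_ms`,
#'   `n_ref`, `n_tgt`, `duration`, `ref`, `tgt`.
#' @examples
#' sp <- spikes(c(0.0, 0.005), c(1L, 2L), t_stop = 1)
#' cross_correlogram(sp, 1, 2)
#' @export
cross_correlogram <- function(x, ref, tgt, window_ms = 50, bin_ms = 1) {
  x <- assert_spikes(x)
  check_cc_grid(window_ms, bin_ms)
  tr <- unit_times(x, ref)
  tt <- unit_times(x, tgt)
  counts <- bin_pair_lags(tr, tt, window_ms, bin_ms, drop_self = 0L)
  new_correlogram(counts, window_ms, bin_ms,
                  n_ref = length(tr), n_tgt = length(tt),
                  duration = duration(x), ref = ref, tgt = tgt)
}

#' Auto-correlogram of a spike train
#'
#' As [cross_correlogram()] with the train against itself. With
#' `include_self = TRUE` every spike also pairs with itself, adding the delta
#' peak of `n` counts at zero lag; with the default `FALSE` self-pairs are
#' removed, which is required before fitting peak-shape models with
#' [cusp_vs_smooth_test()].
#'
#' @param x A `spikes` data frame.
#' @param unit Unit id; `NULL` allowed when only one unit is present.
#' @inheritParams cross_correlogram
#' @param include_self Keep the i = k self-pairs (delta peak)?
#' @return A `correlogram` tibble.
#' @export
auto_correlogram <- function(x, unit = NULL, window_ms = 50, bin_ms = 1,
                             include_self = FALSE) {
  x <- assert_spikes(x)
  check_cc_grid(window_ms, bin_ms)
  tr <- unit_times(x, unit)
  counts <- bin_pair_lags(tr, tr, window_ms, bin_ms,
                          drop_self = if (include_self) 0L else length(tr))
  new_correlogram(counts, window_ms, bin_ms,
                  n_ref = length(tr), n_tgt = length(tr),
                  duration = duration(x),
                  ref = unit %||% unique(x$unit), tgt = unit %||% unique(x$unit))
}

check_cc_grid <- function(window_ms, bin_ms) {
  if (window_ms <= 0 || bin_ms <= 0) stop("window and bin must be positive", call. = FALSE)
  k <- window_ms / bin_ms
  if (abs(k - round(k)) > 1e-9) {
    stop("`window_ms` must be an integer multiple of `bin_ms`", call. = FALSE)
  }
}

# Enumerate lags of all ordered (ref, tgt) pairs within +/- W and tabulate.
# Vectorized via findInterval on the sorted target train; `drop_self` counts
# are removed from the zero-lag bin (auto-correlogram without self-pairs).
bin_pair_lags <- function(tr, tt, window_ms, bin_ms, drop_self = 0L) {
  w_s <- window_ms / 1000
  n_bins <- as.integer(round(2 * window_ms / bin_ms))
  if (!length(tr) || !length(tt)) return(integer(n_bins))
  lo <- findInterval(tr - w_s - 1e-12, tt)
  hi <- findInterval(tr + w_s + 1e-12, tt)
  m <- hi - lo
  sel <- m > 0L
  if (!any(sel)) return(integer(n_bins))
  tgt_idx <- sequence(m[sel], from = lo[sel] + 1L)
  lags_ms <- (tt[tgt_idx] - rep(tr[sel], m[sel])) * 1000
  bin <- floor((lags_ms + window_ms) / bin_ms) + 1
  keep <- bin >= 1 & bin <= n_bins
  counts <- tabulate(bin[keep], n_bins)
  if (drop_self > 0L) {
    zero_bin <- as.integer(window_ms / bin_ms) + 1L
    counts[zero_bin] <- counts[zero_bin] - drop_self
  }
  counts
}

new_correlogram <- function(counts, window_ms, bin_ms, n_ref, n_tgt, duration,
                            ref = NA, tgt = NA) {
  edges <- seq(-window_ms, window_ms, by = bin_ms)
  tibble::new_tibble(
    tibble::tibble(
      lag_left = edges[-length(edges)],
      lag_right = edges[-1],
      count = as.integer(counts)
    ),
    window_ms = window_ms, bin_ms = bin_ms,
    n_ref = n_ref, n_tgt = n_tgt, duration = duration,
    ref = ref, tgt = tgt,
    class = "correlogram"
  )
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("# Correlogram: W = %g ms, bin = %g ms, %d pairs counted (n_ref = %d, n_tgt = %d)\n",
              attr(x, "window_ms"), attr(x, "bin_ms"), sum(x$count),
              attr(x, "n_ref"), attr(x, "n_tgt")))
  NextMethod()
}

cc_centers <- function(cc) (cc$lag_left + cc$lag_right) / 2

#' Reverse a correlogram's lag axis
#'
#' Returns the correlogram of the swapped pair: `c_ji(t) = c_ij(-t)` holds
#' exactly, so swapping reference and target only reverses the bin order.
#'
#' @param cc A `correlogram` tibble.
#' @return A `correlogram` tibble for the opposite direction.
#' @export
reverse_correlogram <- function(cc) {
  new_correlogram(rev(cc$count), attr(cc, "window_ms"), attr(cc, "bin_ms"),
                  n_ref = attr(cc, "n_tgt"), n_tgt = attr(cc, "n_ref"),
                  duration = attr(cc, "duration"),
                  ref = attr(cc, "tgt"), tgt = attr(cc, "ref"))
}

#' Export a correlogram as delimited text
#'
#' Writes columns `lag_left_ms`, `lag_right_ms`, `count`, tab-separated.
#' @param cc A `correlogram` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlogram <- function(cc, path) {
  utils::write.table(
    data.frame(lag_left_ms = cc$lag_left, lag_right_ms = cc$lag_right, count = cc$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Averaged power spectrum of a binned spike train
#'
#' Bins the train, splits it into non-overlapping segments, and averages the
#' periodograms of the mean-subtracted segment counts (Bartlett's method). A
#' homogeneous Poisson train gives a flat (white) spectrum; coherent
#' oscillatory modulation of the population shows up as a spectral hump at
#' the modulation frequency.
#'
#' @param x A `spikes` data frame (typically the summed train).
#' @param bin_ms Count bin in ms (default 1).
#' @param segment_s Segment length in seconds (default 10). The recording
#'   must contain at least one full segment.
#' @return A tibble with `frequency` (Hz) and `power`.
#' @export
power_spectrum <- function(x, bin_ms = 1, segment_s = 10) {
  x <- assert_spikes(x)
  if (duration(x) < segment_s) {
    stop("recording shorter than one spectral segment", call. = FALSE)
  }
  h <- time_histogram(x, bin_width = bin_ms / 1000)
  n_per <- as.integer(round(segment_s / (bin_ms / 1000)))
  n_seg <- floor(nrow(h) / n_per)
  counts <- h$count[seq_len(n_seg * n_per)]
  seg <- matrix(counts, nrow = n_per, ncol = n_seg)
  seg <- sweep(seg, 2, colMeans(seg))
  pg <- abs(stats::mvfft(seg))^2 / n_per
  n_keep <- floor(n_per / 2)
  tibble::tibble(
    frequency = (1:n_keep) / segment_s,
    power = rowMeans(pg, na.rm = FALSE)[2:(n_keep + 1)]
  )
}
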