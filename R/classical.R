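#' Classical cross-correlogram significance test
#'
#' The baseline flat-null test: the correlogram of an unconnected pair is
#' assumed flat, so a monosynaptic connection is declared when any bin inside
#' the detection window (a few ms from the origin) escapes a Poisson
#' confidence band around the flat baseline — a hump above the band is read
#' as excitatory, a dip below as inhibitory. The baseline is the mean count
#' over bins with `|lag|` beyond 10 ms; the band uses exact Poisson quantiles
#' at level `alpha` Bonferroni-corrected for the total number of tested bins.
#' Direction ref-to-target is tested on the positive-lag window, the reverse
#' on its mirror image.
#'
#' Because the flat null ignores common-input structure, this test is known
#' to report many spurious connections whenever the correlogram undulates or
#' has a cusp; it is provided as the reference method.
#'
#' @param cc A `correlogram` tibble.
#' @param alpha Significance level (default `1e-4`, matching the GLM tests).
#' @param detect_window Lag interval in ms tested for a connection
#'   (default `c(1, 5)`).
#' @param baseline_min_ms Bins with `|lag|` beyond this (ms) form the
#'   baseline region (default 10).
#' @return A tibble of class `classical_result` with one row per direction:
#'   `ref`, `tgt`, `sign`, `extreme_lag`, `extreme_count`, plus attributes
#'   `baseline`, `band_low`, `band_high`.
#' @export
classical_test <- function(cc, alpha = 1e-4, detect_window = c(1, 5),
                           baseline_min_ms = 10) {
  if (!nrow(cc)) stop("empty correlogram", call. = FALSE)
  ctr <- cc_centers(cc)
  base_sel <- abs(ctr) > baseline_min_ms
  pos_sel <- cc$lag_left >= detect_window[1] & cc$lag_right <= detect_window[2]
  neg_sel <- cc$lag_right <= -detect_window[1] & cc$lag_left >= -detect_window[2]
  if (sum(base_sel) < 20L) {
    stop("need at least 20 bins outside the detection window for the baseline",
         call. = FALSE)
  }
  baseline <- mean(cc$count[base_sel])
  n_test <- sum(pos_sel) + sum(neg_sel)
  a2 <- alpha / n_test
  band_low <- stats::qpois(a2 / 2, baseline)
  band_high <- stats::qpois(1 - a2 / 2, baseline)

  decide <- function(sel) {
    cnt <- cc$count[sel]
    lagm <- ctr[sel]
    hit_hi <- cnt > band_high
    hit_lo <- cnt < band_low
    if (!any(hit_hi) && !any(hit_lo)) {
      k <- which.max(abs(cnt - baseline))
      return(list(sign = "none", lag = lagm[k], count = cnt[k]))
    }
    dev <- abs(cnt - baseline)
    dev[!(hit_hi | hit_lo)] <- -Inf
    k <- which.max(dev)
    list(sign = if (cnt[k] > baseline) "excitatory" else "inhibitory",
         lag = lagm[k], count = cnt[k])
  }
  fwd <- decide(pos_sel)
  rev_ <- decide(neg_sel)
  tibble::new_tibble(
    tibble::tibble(
      ref = c(attr(cc, "ref"), attr(cc, "tgt")),
      tgt = c(attr(cc, "tgt"), attr(cc, "ref")),
      sign = c(fwd$sign, rev_$sign),
      extreme_lag = c(fwd$lag, rev_$lag),
      extreme_count = c(fwd$count, rev_$count)
    ),
    baseline = baseline, band_low = band_low, band_high = band_high,
    alpha = alpha,
    class = "classical_result"
  )
}
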