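#' Build a spike data frame
#'
#' The package's central data structure is a tibble of spike events with a
#' `time` column (seconds) and an integer `unit` column, carrying the shared
#' recording span `[t_start, t_stop]` as attributes. All analysis functions
#' take such a data frame first, so calls chain with the pipe.
#'
#' @param time Numeric vector of spike times in seconds.
#' @param unit Integer vector of unit labels (recycled if length 1).
#' @param t_start,t_stop Recording span in seconds. If omitted, inferred as
#'   `0` and the maximum spike time rounded up to the next second.
#' @param duplicates How to treat duplicate timestamps within a unit:
#'   `"error"` (default) rejects them, `"collapse"` keeps one copy.
#'   Coincident spikes of *different* units are always allowed.
#' @return A tibble of class `spikes` with columns `time` and `unit`, sorted
#'   by unit then time, with attributes `t_start` and `t_stop`.
#' @examples
#' sp <- spikes(c(0.1, 0.3, 0.2), c(1L, 1L, 2L))
#' n_spikes(sp)
#' @export
spikes <- function(time, unit = 1L, t_start = NULL, t_stop = NULL,
                   duplicates = c("error", "collapse")) {
  duplicates <- match.arg(duplicates)
  if (!is.numeric(time)) stop("`time` must be numeric (seconds)", call. = FALSE)
  unit <- as.integer(unit)
  if (length(unit) == 1L) unit <- rep(unit, length(time))
  if (length(unit) != length(time)) stop("`unit` must match `time` in length", call. = FALSE)
  if (anyNA(time) || anyNA(unit)) stop("spike times/units must not be NA", call. = FALSE)
  if (any(unit < 0L)) stop("unit ids must be non-negative integers", call. = FALSE)
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_stop)) t_stop <- if (length(time)) max(ceiling(max(time)), t_start + 1) else t_start + 1
  if (t_stop <= t_start) stop("`t_stop` must exceed `t_start`", call. = FALSE)
  if (length(time) && (min(time) < t_start || max(time) > t_stop)) {
    stop("spike times outside the recording span [", t_start, ", ", t_stop, "]",
         call. = FALSE)
  }
  df <- tibble::tibble(time = as.numeric(time), unit = unit)
  df <- dplyr::arrange(df, .data$unit, .data$time)
  dup <- duplicated(df)
  if (any(dup)) {
    if (duplicates == "error") {
      stop("duplicate spike times within a unit; use duplicates = \"collapse\"",
           call. = FALSE)
    }
    df <- df[!dup, ]
  }
  new_spikes(df, t_start, t_stop)
}

new_spikes <- function(df, t_start, t_stop) {
  tibble::new_tibble(df, t_start = as.numeric(t_start), t_stop = as.numeric(t_stop),
                     class = "spikes")
}

#' @export
print.spikes <- function(x, ...) {
  cat(sprintf("# Spike data: %d units, %d spikes, span [%g, %g] s\n",
              dplyr::n_distinct(x$unit), nrow(x), t_start(x), t_stop(x)))
  NextMethod()
}

#' Recording span accessors
#'
#' @param x A `spikes` data frame.
#' @return Start/stop time or duration of the recording, in seconds.
#' @export
t_start <- function(x) attr(x, "t_start")

#' @rdname t_start
#' @export
t_stop <- function(x) attr(x, "t_stop")

#' @rdname t_start
#' @export
duration <- function(x) t_stop(x) - t_start(x)

#' @rdname t_start
#' @export
n_spikes <- function(x) nrow(x)

#' Extract the spike-time vector of one unit
#' @param x A `spikes` data frame.
#' @param unit Unit id; if `NULL` and only one unit is present, that unit.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
unit_times <- function(x, unit = NULL) {
  if (is.null(unit)) {
    u <- unique(x$unit)
    if (length(u) > 1L) stop("several units present; specify `unit`", call. = FALSE)
    unit <- u
  }
  sort(x$time[x$unit == unit])
}

assert_spikes <- function(x) {
  if (!inherits(x, "spikes")) {
    if (is.data.frame(x) && all(c("time", "unit") %in% names(x))) {
      return(spikes(x$time, x$unit))
    }
    stop("expected a `spikes` data frame (see `spikes()`)", call. = FALSE)
  }
  x
}

#' Read parallel spike trains from delimited text
#'
#' Parses the common two-column spike export: one event per row, spike time in
#' seconds and integer unit id, whitespace- or comma-delimited, with an
#' optional header that is auto-detected.
#'
#' @param path File path.
#' @param span Optional numeric `c(t_start, t_stop)`. If omitted, the span is
#'   inferred as `(0, max time rounded up)`. Times outside an explicit span
#'   raise a validation error.
#' @inheritParams spikes
#' @return A `spikes` data frame (see [spikes()]).
#' @export
read_spike_trains <- function(path, span = NULL, duplicates = c("error", "collapse")) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines_kept <- lines[keep]
  lineno <- which(keep)
  if (!length(lines_kept)) stop("empty spike file: ", path, call. = FALSE)
  delim <- if (grepl(",", lines_kept[[1]], fixed = TRUE)) "," else "[[:space:]]+"
  parts <- strsplit(trimws(lines_kept), delim)
  bad_shape <- which(lengths(parts) < 2L)
  if (length(bad_shape)) {
    stop("parse error at line ", lineno[bad_shape[[1]]], " of ", path,
         ": expected two columns (time_s, unit_id)", call. = FALSE)
  }
  first <- suppressWarnings(as.numeric(parts[[1]][1:2]))
  has_header <- anyNA(first)
  if (has_header) {
    parts <- parts[-1]
    lineno <- lineno[-1]
    if (!length(parts)) stop("spike file has a header but no data: ", path, call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  un <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(tm) | is.na(un) | un != floor(un))
  if (length(bad)) {
    stop("parse error at line ", lineno[bad[[1]]], " of ", path,
         ": malformed row", call. = FALSE)
  }
  if (!is.null(span)) {
    out <- which(tm < span[[1]] | tm > span[[2]])
    if (length(out)) {
      stop("spike time at line ", lineno[out[[1]]],
           " outside the stated span [", span[[1]], ", ", span[[2]], "]",
           call. = FALSE)
    }
    spikes(tm, as.integer(un), span[[1]], span[[2]], duplicates = duplicates)
  } else {
    spikes(tm, as.integer(un), duplicates = duplicates)
  }
}

#' Write spike trains as two-column delimited text
#'
#' Inverse of [read_spike_trains()]: rows are `time_s unit_id`, time printed
#' with nanosecond precision so a read/write round trip is the identity.
#'
#' @param x A `spikes` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(x, path) {
  x <- assert_spikes(x)
  ord <- order(x$time, x$unit)
  writeLines(sprintf("%.9f %d", x$time[ord], x$unit[ord]), path)
  invisible(path)
}

#' Merge all units into one summed spike train
#'
#' Pools the spike times of every unit into a single train (unit id 0), the
#' device used to expose population-level rate fluctuations: slow oscillation
#' and nondifferentiable background activity both survive the summation.
#' Coincident spikes of different units are retained.
#'
#' @param x A `spikes` data frame with at least one spike.
#' @return A `spikes` data frame with a single unit `0`.
#' @export
sum_trains <- function(x) {
  x <- assert_spikes(x)
  if (!nrow(x)) stop("cannot sum an empty spike dataset", call. = FALSE)
  new_spikes(tibble::tibble(time = sort(x$time), unit = 0L), t_start(x), t_stop(x))
}

#' Time histogram of a spike train
#'
#' Bins events over the recording span; the partial last bin is padded so the
#' edges cover the whole span and counts conserve the number of spikes.
#'
#' @param x A `spikes` data frame (typically a single or summed train).
#' @param bin_width Bin width in seconds (default 0.01, i.e. 10 ms).
#' @return A tibble with `bin_left`, `bin_right` (seconds) and integer `count`.
#' @export
time_histogram <- function(x, bin_width = 0.01) {
  x <- assert_spikes(x)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a positive scalar (seconds)", call. = FALSE)
  }
  n_bins <- max(1L, ceiling((duration(x) - 1e-12) / bin_width))
  edges <- t_start(x) + bin_width * (0:n_bins)
  idx <- pmin(pmax(floor((x$time - t_start(x)) / bin_width) + 1L, 1L), n_bins)
  tibble::tibble(
    bin_left = edges[-length(edges)],
    bin_right = edges[-1],
    count = tabulate(idx, n_bins)
  )
}

#' Jitter (dither) surrogate
#'
#' Displaces each spike independently by a uniform offset on `[-half_width,
#' +half_width]`, clipped to the recording span. Jittering by a few
#' milliseconds destroys spike-time structure sharper than the jitter scale,
#' so a genuine correlogram cusp collapses into a smooth hump while slow
#' undulation survives.
#'
#' @param x A `spikes` data frame.
#' @param half_width Jitter half-width in seconds (> 0).
#' @param seed Integer seed; identical seed gives identical output.
#' @return A `spikes` data frame with per-unit spike counts preserved.
#' @export
jitter_surrogate <- function(x, half_width, seed) {
  x <- assert_spikes(x)
  if (!is.numeric(half_width) || half_width <= 0) {
    stop("`half_width` must be > 0 (seconds)", call. = FALSE)
  }
  tm <- withr::with_seed(as.integer(seed), {
    x$time + stats::runif(nrow(x), -half_width, half_width)
  })
  tm <- pmin(pmax(tm, t_start(x)), t_stop(x))
  df <- dplyr::arrange(tibble::tibble(time = tm, unit = x$unit), .data$unit, .data$time)
  new_spikes(df, t_start(x), t_stop(x))
}

#' Inter-spike-interval shuffle surrogate
#'
#' Per unit, randomly permutes the inter-spike intervals and re-accumulates
#' them from the first spike time. The per-unit ISI multiset (hence rate and
#' ISI statistics) is preserved exactly while cross-unit timing and slow
#' co-modulation are destroyed, giving a temporal-variability reference for
#' population rasters and histograms.
#'
#' @param x A `spikes` data frame.
#' @param seed Integer seed.
#' @return A `spikes` data frame.
#' @export
shuffle_surrogate <- function(x, seed) {
  x <- assert_spikes(x)
  if (!nrow(x)) stop("cannot shuffle an empty spike dataset", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    parts <- lapply(split(x$time, x$unit), function(tt) {
      tt <- sort(tt)
      if (length(tt) <= 2L) {
        tt
      } else {
        tt[1] + cumsum(c(0, sample(diff(tt))))
      }
    })
    df <- tibble::tibble(
      time = unlist(parts, use.names = FALSE),
      unit = rep(as.integer(names(parts)), lengths(parts))
    )
    new_spikes(dplyr::arrange(df, .data$unit, .data$time), t_start(x), t_stop(x))
  })
}
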