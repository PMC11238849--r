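#' Cusp-versus-smooth peak model comparison
#'
#' Decides whether the central peak of an auto-correlogram is a nonsmooth
#' cusp or a smooth hump. A correlogram peak can only be nondifferentiable at
#' the origin if the underlying common rate process is not mean-square
#' differentiable, so this comparison is a diagnostic for nondifferentiable
#' background activity. Two peak models are fitted to the central bins by
#' maximum Poisson likelihood:
#'
#' * cusp: `mu(t) = b + A * exp(-|t| / tau)` (continuous, kinked at 0);
#' * smooth: `mu(t) = b + A * exp(-t^2 / (2 s^2))` (differentiable everywhere).
#'
#' The self-pair delta peak must already be removed (use
#' `auto_correlogram(..., include_self = FALSE)`).
#'
#' @param acg A `correlogram` tibble (auto-correlogram, self-pairs excluded).
#' @param peak_halfwidth Half-width of the fitted peak region in ms
#'   (default 10); at least 5 bins must fall inside it.
#' @return A one-row tibble of class `cusp_test` with `loglik_cusp`,
#'   `loglik_smooth`, `delta` (their difference) and `preferred`
#'   (`"cusp"` iff `delta > 0`).
#' @export
cusp_vs_smooth_test <- function(acg, peak_halfwidth = 10) {
  ctr <- cc_centers(acg)
  sel <- abs(ctr) <= peak_halfwidth
  if (sum(sel) < 5L) {
    stop("fewer than 5 bins in the peak region; widen `peak_halfwidth`", call. = FALSE)
  }
  t <- ctr[sel]
  y <- acg$count[sel]
  base0 <- max(mean(acg$count[!sel]), mean(y), 1e-3)
  amp0 <- max(max(y) - base0, base0 * 0.1, 1e-3)

  nll <- function(mu, y) {
    mu <- pmax(mu, 1e-10)
    -sum(stats::dpois(y, mu, log = TRUE))
  }
  fit_shape <- function(shape_fun, width0) {
    obj <- function(p) nll(p[1] + p[2] * shape_fun(t, p[3]), y)
    best <- NULL
    for (w0 in width0 * c(0.5, 1, 2)) {
      f <- stats::optim(c(base0, amp0, w0), obj, method = "L-BFGS-B",
                        lower = c(1e-8, 0, 0.1), upper = c(Inf, Inf, 1e3))
      if (is.null(best) || f$value < best$value) best <- f
    }
    best
  }
  fit_c <- fit_shape(function(t, w) exp(-abs(t) / w), peak_halfwidth / 3)
  fit_s <- fit_shape(function(t, w) exp(-t^2 / (2 * w^2)), peak_halfwidth / 3)
  ll_c <- -fit_c$value
  ll_s <- -fit_s$value
  tibble::new_tibble(
    tibble::tibble(
      loglik_cusp = ll_c,
      loglik_smooth = ll_s,
      delta = ll_c - ll_s,
      preferred = if (ll_c - ll_s > 0) "cusp" else "smooth"
    ),
    class = "cusp_test"
  )
}
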