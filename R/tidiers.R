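#' Tidy a correlogram GLM fit
#'
#' One row per lag bin with the fitted background and total intensity.
#'
#' @param x A `glmcc_fit` object.
#' @param ... Unused.
#' @return A tibble with `lag_mid`, `count`, `a`, `fitted`.
#' @export
tidy.glmcc_fit <- function(x, ...) {
  tibble::tibble(
    lag_mid = x$lag_mid,
    count = x$counts,
    a = x$a,
    fitted = x$fitted
  )
}

#' @rdname tidy.glmcc_fit
#' @return For `glance()`: a one-row tibble with the couplings, kernel
#'   parameters, likelihoods and convergence information.
#' @export
glance.glmcc_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, J_pos = x$J_pos, J_neg = x$J_neg,
    tau_s = x$tau_s, d = x$d,
    loglik = x$loglik, logpost = x$logpost,
    converged = x$converged, iterations = x$iterations
  )
}

#' Tidy a pair decision
#'
#' One row per direction with coupling, likelihood-ratio statistic and label.
#'
#' @param x A `pair_decision` object.
#' @param ... Unused.
#' @return A tibble with `pre`, `post`, `J`, `D`, `detected`, `sign`.
#' @export
tidy.pair_decision <- function(x, ...) {
  tibble::tibble(
    pre = c(x$ref, x$tgt), post = c(x$tgt, x$ref),
    J = c(x$J_pos, x$J_neg), D = c(x$D_pos, x$D_neg),
    detected = 2 * c(x$D_pos, x$D_neg) > x$z_alpha,
    sign = c(x$sign_pos, x$sign_neg)
  )
}

#' @rdname tidy.pair_decision
#' @export
glance.pair_decision <- function(x, ...) {
  tibble::tibble(
    method = x$method, tau_s = x$tau_s, d = x$d,
    z_alpha = x$z_alpha, alpha = x$alpha, converged = x$converged
  )
}

#' Summary of a connection matrix
#'
#' @param x A `connection_matrix` tibble.
#' @param ... Unused.
#' @return A one-row tibble with unit, pair and edge counts.
#' @export
glance.connection_matrix <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    n_units = length(attr(x, "units")),
    n_pairs = nrow(x),
    n_excitatory = sum(x$sign == "excitatory"),
    n_inhibitory = sum(x$sign == "inhibitory"),
    n_failed = sum(x$sign == "failed")
  )
}

#' Tidy an evaluation result
#'
#' @param x An `eval_result` object.
#' @param ... Unused.
#' @return The per-category score tibble.
#' @export
tidy.eval_result <- function(x, ...) x$per_category

#' @rdname tidy.eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(macro_mcc = x$macro_mcc)
}
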