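#' Estimate a full directed connection matrix
#'
#' Applies one of the three detectors to every pair of units: each unordered
#' pair is correlogrammed once and both directions are decided from it, so a
#' dataset of N units yields N(N-1) directed entries. Pairs are independent
#' units of work and the result is deterministic given the data and
#' hyperparameters.
#'
#' @param x A `spikes` data frame with at least two units.
#' @param method `"shin"` (default), `"glmcc"`, or `"classical"`.
#' @param hyper A [hyperparams()] list (its `alpha`, window and grids apply
#'   to all methods; `classical` uses `alpha` and the window only).
#' @param progress Print per-pair progress?
#' @return A tibble of class `connection_matrix` with one row per ordered
#'   pair: `pre`, `post`, `sign`, `J`, `D`, `tau_s`, `d`, `converged`, and
#'   attributes `units` and `method`. Use [edges()] for the detected-edge
#'   list and [ei_dominance()] for per-unit sign consistency.
#' @export
estimate_connectivity <- function(x, method = c("shin", "glmcc", "classical"),
                                  hyper = hyperparams(), progress = FALSE) {
  method <- match.arg(method)
  x <- assert_spikes(x)
  units <- sort(unique(x$unit))
  if (length(units) < 2L) stop("need at least 2 units", call. = FALSE)
  pairs <- utils::combn(units, 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cc <- cross_correlogram(x, i, j, hyper$window_ms, hyper$bin_ms)
    rows[[k]] <- tryCatch(
      decide_both_directions(cc, method, hyper),
      error = function(e) tibble::tibble(
        pre = c(i, j), post = c(j, i), sign = "failed",
        J = NA_real_, D = NA_real_, tau_s = NA_real_, d = NA_real_,
        converged = FALSE
      )
    )
    if (progress) {
      message(sprintf("pair %d/%d (%s, %s)", k, ncol(pairs), i, j))
    }
  }
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, units = units, method = method, hyper = hyper,
                     class = "connection_matrix")
}

decide_both_directions <- function(cc, method, hyper) {
  if (method == "classical") {
    res <- classical_test(cc, alpha = hyper$alpha)
    tibble::tibble(
      pre = res$ref, post = res$tgt, sign = res$sign,
      J = NA_real_, D = NA_real_, tau_s = NA_real_, d = NA_real_,
      converged = TRUE
    )
  } else {
    dec <- lr_decide(cc, method, hyper)
    tibble::tibble(
      pre = c(dec$ref, dec$tgt), post = c(dec$tgt, dec$ref),
      sign = c(dec$sign_pos, dec$sign_neg),
      J = c(dec$J_pos, dec$J_neg), D = c(dec$D_pos, dec$D_neg),
      tau_s = dec$tau_s, d = dec$d, converged = dec$converged
    )
  }
}

#' @export
print.connection_matrix <- function(x, ...) {
  ne <- sum(x$sign == "excitatory")
  ni <- sum(x$sign == "inhibitory")
  cat(sprintf("# Connection matrix (%s): %d units, %d directed pairs, %d excitatory + %d inhibitory edges\n",
              attr(x, "method"), length(attr(x, "units")), nrow(x), ne, ni))
  NextMethod()
}

#' Detected edge list of a connection matrix
#'
#' @param conn A `connection_matrix` tibble.
#' @return The rows with a detected (non-`"none"`) sign.
#' @export
edges <- function(conn) {
  dplyr::filter(conn, !.data$sign %in% c("none", "failed"))
}

#' Excitatory-inhibitory dominance index per sending neuron
#'
#' For each unit, `dei = (ne - ni) / (ne + ni)` over its identified outgoing
#' excitatory (`ne`) and inhibitory (`ni`) connections; `+1`/`-1` mean the
#' unit's detected outputs are all of one sign, as expected for a real neuron
#' obeying Dale's law. Units with no detected outputs get `NA` and are
#' excluded from averages.
#'
#' @param conn A `connection_matrix` tibble.
#' @return A tibble with `unit`, `ne`, `ni`, `dei`.
#' @export
ei_dominance <- function(conn) {
  units <- attr(conn, "units") %||% sort(unique(conn$pre))
  e <- edges(conn)
  out <- dplyr::summarise(
    dplyr::group_by(e, unit = .data$pre),
    ne = sum(.data$sign == "excitatory"),
    ni = sum(.data$sign == "inhibitory"),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(unit = units), out, by = "unit")
  out$ne[is.na(out$ne)] <- 0L
  out$ni[is.na(out$ni)] <- 0L
  out$dei <- ifelse(out$ne + out$ni > 0, (out$ne - out$ni) / (out$ne + out$ni), NA_real_)
  out
}

#' Write an edge list / signed matrix as delimited text
#'
#' `write_edges()` writes the detected edges with columns
#' `pre, post, sign{E,I}, J, D, tau_s_ms, d_ms`; `write_connection_grid()`
#' writes an N-by-N signed grid (+1 excitatory, -1 inhibitory, 0 none).
#'
#' @param conn A `connection_matrix` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(conn, path) {
  e <- edges(conn)
  utils::write.table(
    data.frame(pre = e$pre, post = e$post,
               sign = ifelse(e$sign == "excitatory", "E", "I"),
               J = e$J, D = e$D, tau_s_ms = e$tau_s, d_ms = e$d),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_edges
#' @export
write_connection_grid <- function(conn, path) {
  units <- attr(conn, "units")
  n <- length(units)
  g <- matrix(0L, n, n, dimnames = list(units, units))
  e <- edges(conn)
  g[cbind(match(e$pre, units), match(e$post, units))] <-
    ifelse(e$sign == "excitatory", 1L, -1L)
  utils::write.table(g, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
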