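#' Confusion counts of an estimated connection matrix against ground truth
#'
#' Scores estimated directed edges per category (excitatory, inhibitory).
#' Ground-truth excitatory positives are edges whose conductance *before*
#' the strength multiplier exceeds `exc_floor` (default 0.01); weaker
#' excitatory edges are dropped from the excitatory universe entirely — they
#' are too faint to be detectable in principle, so they count neither as
#' positives nor as negatives. The inhibitory category uses all inhibitory
#' edges. An estimated edge is a true positive only when its sign matches
#' the category; a sign-flipped detection is therefore a false negative in
#' the true category and a false positive in the detected one.
#'
#' @param truth A `mat_connectivity` object, or a tibble with columns
#'   `pre`, `post`, `type` (`"exc"`/`"inh"`), `weight` (pre-multiplier
#'   conductance) plus a `units` attribute or covering all evaluated units.
#' @param est A `connection_matrix` tibble (its `units` attribute must match
#'   the truth's unit set).
#' @param exc_floor Excitatory detectability floor on the pre-multiplier
#'   conductance.
#' @return A tibble with one row per category: `category`, `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_counts <- function(truth, est, exc_floor = 0.01) {
  tr <- as_truth_edges(truth)
  units <- attr(est, "units")
  if (is.null(units)) units <- sort(unique(c(est$pre, est$post)))
  if (!setequal(attr(tr, "units"), units)) {
    stop("unit sets of truth and estimate do not match", call. = FALSE)
  }
  key <- function(a, b) paste(a, b, sep = "->")
  est_eval <- est[est$pre %in% units & est$post %in% units, ]
  all_keys <- key(est_eval$pre, est_eval$post)

  tr <- tr[tr$pre %in% units & tr$post %in% units, ]
  exc_strong <- key(tr$pre[tr$type == "exc" & tr$weight > exc_floor],
                    tr$post[tr$type == "exc" & tr$weight > exc_floor])
  exc_weak <- key(tr$pre[tr$type == "exc" & tr$weight <= exc_floor],
                  tr$post[tr$type == "exc" & tr$weight <= exc_floor])
  inh_true <- key(tr$pre[tr$type == "inh"], tr$post[tr$type == "inh"])

  est_e <- all_keys[est_eval$sign == "excitatory"]
  est_i <- all_keys[est_eval$sign == "inhibitory"]

  count_cat <- function(universe, positives, predicted) {
    pos <- intersect(positives, universe)
    prd <- intersect(predicted, universe)
    TP <- length(intersect(prd, pos))
    FP <- length(setdiff(prd, pos))
    FN <- length(setdiff(pos, prd))
    TN <- length(universe) - TP - FP - FN
    c(TP = TP, FP = FP, FN = FN, TN = TN)
  }
  uni_e <- setdiff(all_keys, exc_weak)
  uni_i <- all_keys
  ce <- count_cat(uni_e, exc_strong, est_e)
  ci <- count_cat(uni_i, inh_true, est_i)
  tibble::tibble(
    category = c("excitatory", "inhibitory"),
    TP = c(ce[["TP"]], ci[["TP"]]), FP = c(ce[["FP"]], ci[["FP"]]),
    FN = c(ce[["FN"]], ci[["FN"]]), TN = c(ce[["TN"]], ci[["TN"]])
  )
}

as_truth_edges <- function(truth) {
  if (inherits(truth, "mat_connectivity")) {
    idx <- which(truth$weights_base != 0, arr.ind = TRUE)
    out <- tibble::tibble(
      pre = idx[, 1], post = idx[, 2],
      type = truth$types[idx[, 1]],
      weight = truth$weights_base[idx]
    )
    attr(out, "units") <- seq_along(truth$types)
    out
  } else if (is.data.frame(truth) &&
             all(c("pre", "post", "type", "weight") %in% names(truth))) {
    if (is.null(attr(truth, "units"))) {
      attr(truth, "units") <- sort(unique(c(truth$pre, truth$post)))
    }
    truth
  } else {
    stop("`truth` must be a mat_connectivity or a (pre, post, type, weight) table",
         call. = FALSE)
  }
}

#' Performance scores from confusion counts
#'
#' Computes per-category false positive rate `FP/(FP+TN)`, false negative
#' rate `FN/(FN+TP)` and Matthews correlation coefficient, plus the
#' macro-averaged `MCC = (MCC_e + MCC_i)/2` that weighs both categories
#' equally. Any MCC with a zero denominator is defined as 0.
#'
#' @param counts A tibble as returned by [confusion_counts()].
#' @return A list of class `eval_result`: `per_category` tibble with `FPR`,
#'   `FNR`, `MCC` added, and `macro_mcc`.
#' @export
scores <- function(counts) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(counts)))
  mcc1 <- function(TP, FP, FN, TN) {
    den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    if (den == 0) return(0)
    (TP * TN - FP * FN) / den
  }
  per <- dplyr::mutate(
    counts,
    FPR = ifelse(.data$FP + .data$TN > 0, .data$FP / (.data$FP + .data$TN), 0),
    FNR = ifelse(.data$FN + .data$TP > 0, .data$FN / (.data$FN + .data$TP), 0),
    MCC = purrr::pmap_dbl(list(as.numeric(.data$TP), as.numeric(.data$FP),
                               as.numeric(.data$FN), as.numeric(.data$TN)), mcc1)
  )
  structure(list(per_category = per, macro_mcc = mean(per$MCC)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("# Connectivity evaluation\n")
  print(x$per_category)
  cat(sprintf("macro MCC = %.4f\n", x$macro_mcc))
  invisible(x)
}

#' One-call evaluation of an estimate against ground truth
#'
#' @inheritParams confusion_counts
#' @return An `eval_result` (see [scores()]).
#' @export
evaluate_connectivity <- function(truth, est, exc_floor = 0.01) {
  scores(confusion_counts(truth, est, exc_floor))
}
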