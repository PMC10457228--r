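# ROC construction, AUC, Youden operating point, per-tissue false-positive
# breakdown. Classification rule, stated once and used everywhere:
# score >= threshold  ->  tumor.

#' Build a ROC curve
#'
#' The curve is evaluated at every unique score value as a threshold
#' (equal scores are grouped into one threshold step), with the endpoints
#' (0, 0) and (1, 1) included. The AUC is the trapezoidal integral of the
#' curve, which for mid-rank tie handling equals the Mann-Whitney
#' `U / (n1 * n2)`.
#'
#' @param scores Finite numeric scores, higher = more tumor-like.
#' @param labels Logical vector, `TRUE` for the positive (tumor) class.
#' @return An object of class `roc_result`: `thresholds` (decreasing,
#'   starting at `Inf`), `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!any(labels) || all(labels))
    stop("both classes must be present to build a ROC curve")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), 0)
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' Youden operating point of a ROC curve
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1
#' (equivalently TPR - FPR). Ties are broken towards higher specificity,
#' then towards the lower threshold.
#'
#' @param roc A `roc_result`.
#' @return List: `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$tpr - roc$fpr
  best <- order(-j, roc$fpr, roc$thresholds)[1]
  list(threshold = roc$thresholds[best], sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best], j = j[best])
}

#' Per-tissue false-positive breakdown
#'
#' For every non-cancerous tissue type present among the labels, the
#' fraction of its spectra scored at or above the decision threshold
#' (i.e. falsely identified as tumor). Types with no spectra are reported
#' as absent, not as zero.
#'
#' @param scores Numeric classifier scores.
#' @param tissue_labels Character tissue labels aligned with `scores`.
#' @param threshold Decision threshold (from [youden_point()]).
#' @return Data frame of class `fp_breakdown`: `tissue`, `n`, `n_fp`,
#'   `fraction`, ordered by decreasing fraction.
#' @export
fp_breakdown <- function(scores, tissue_labels, threshold) {
  stopifnot(length(scores) == length(tissue_labels))
  types <- intersect(NONCANCER_LABELS, unique(tissue_labels))
  rows <- lapply(types, function(t) {
    sel <- tissue_labels == t
    data.frame(tissue = t, n = sum(sel),
               n_fp = sum(scores[sel] >= threshold))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tissue = character(0), n = integer(0),
                      n_fp = integer(0))
  out$fraction <- if (nrow(out)) out$n_fp / out$n else numeric(0)
  out <- out[order(-out$fraction, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fp_breakdown", "data.frame")
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}
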