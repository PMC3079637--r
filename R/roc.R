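#' Receiver operating characteristic of a ranked candidate list
#'
#' Builds the ROC step curve for a score vector against binary labels
#' (higher score = stronger evidence for the positive class) and computes
#' the three summary metrics used for screen evaluation: the full area under
#' the curve (AUC), the normalized partial AUC over a small false-positive
#' range, and the early sensitivity (TPR at a small fixed FPR).
#'
#' Tied scores are collapsed into single thresholds, so groups of ties
#' contribute diagonal segments; with trapezoidal integration the AUC then
#' equals the Mann-Whitney statistic (fraction of concordant
#' positive/negative pairs, ties counted as one half).
#'
#' @param scores Numeric vector of prediction scores (no `NA`).
#' @param labels Binary vector (0/1 or logical) of true classes, aligned
#'   with `scores`; both classes must be present.
#' @param pauc_r Upper FPR bound for the normalized partial AUC
#'   (default 0.1).
#' @param early_fpr FPR cut for the early sensitivity (default 0.01).
#'
#' @return An object of class `roc_result`: list with `fpr`, `tpr` (step
#'   curve from (0,0) to (1,1)), `n_pos`, `n_neg`, `auc`, `pauc`, `pauc_r`,
#'   `early_tpr`, `early_fpr`.
#' @examples
#' r <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
#' r$auc # 0.75
#' @export
roc_curve <- function(scores, labels, pauc_r = 0.1, early_fpr = 0.01) {
  if (is.logical(labels)) labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (length(scores) != length(labels) || length(scores) == 0) {
    stop("scores and labels must be non-empty aligned vectors", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # collapse tied thresholds: keep the last index of each distinct score
  last <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  fpr <- c(0, fp / n_neg)
  tpr <- c(0, tp / n_pos)
  auc <- trapezoid_area(fpr, tpr)
  res <- structure(
    list(
      fpr = fpr, tpr = tpr, n_pos = n_pos, n_neg = n_neg, auc = auc,
      pauc = NA_real_, pauc_r = pauc_r, early_tpr = NA_real_,
      early_fpr = early_fpr
    ),
    class = "roc_result"
  )
  res$pauc <- partial_auc(res, pauc_r)
  res$early_tpr <- early_sensitivity(res, early_fpr)
  res
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Normalized partial AUC over a restricted false-positive range
#'
#' Integrates the ROC curve over FPR in `[0, r]` (linear interpolation at
#' `r`) and divides the area by `r`. A perfect classifier scores 1; the
#' chance diagonal scores `r^2 / 2` before normalization, hence `r / 2`
#' after it (0.05 at `r = 0.1`). `partial_auc(roc, 1)` equals the full AUC.
#'
#' @param roc A `roc_result`.
#' @param r Upper FPR bound in `(0, 1]`.
#' @return The normalized partial area, in `[0, 1]`.
#' @export
partial_auc <- function(roc, r = 0.1) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r <= 0 || r > 1) {
    stop("r must lie in (0, 1]", call. = FALSE)
  }
  # clip each polyline segment at FPR = r; vertical segments have zero
  # width and contribute nothing, so ties in FPR need no special casing
  x1 <- utils::head(roc$fpr, -1)
  x2 <- utils::tail(roc$fpr, -1)
  y1 <- utils::head(roc$tpr, -1)
  y2 <- utils::tail(roc$tpr, -1)
  xr <- pmin(x2, r)
  w <- pmax(0, xr - x1)
  yr <- ifelse(x2 > x1, y1 + (y2 - y1) * (xr - x1) / pmax(x2 - x1, 1e-300), y2)
  sum(w * (y1 + yr) / 2) / r
}

#' Early sensitivity: TPR at a small fixed FPR
#'
#' Reads the true positive rate of the step curve at the largest achieved
#' FPR at or below `fpr0`, without interpolation. When no threshold achieves
#' an FPR that small (fewer than `1 / fpr0` negatives), this is the TPR at
#' FPR = 0, a conservative value.
#'
#' @param roc A `roc_result`.
#' @param fpr0 FPR cut in `(0, 1)`; default 0.01.
#' @return The TPR value in `[0, 1]`.
#' @export
early_sensitivity <- function(roc, fpr0 = 0.01) {
  if (!is.numeric(fpr0) || length(fpr0) != 1 || is.na(fpr0) ||
    fpr0 <= 0 || fpr0 >= 1) {
    stop("fpr0 must lie strictly between 0 and 1", call. = FALSE)
  }
  max(roc$tpr[roc$fpr <= fpr0])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> %d positives vs %d negatives\n  AUC %.4f | pAUC(r=%g) %.4f | TPR@FPR %g: %.4f\n",
    x$n_pos, x$n_neg, x$auc, x$pauc_r, x$pauc, x$early_fpr, x$early_tpr
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the points of a ROC curve
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A tibble with columns `fpr`, `tpr`.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(fpr = x$fpr, tpr = x$tpr)
}

#' One-row summary of a ROC evaluation
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A tibble with `auc`, `pauc`, `pauc_r`, `early_tpr`, `early_fpr`,
#'   `n_pos`, `n_neg`.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, pauc = x$pauc, pauc_r = x$pauc_r,
    early_tpr = x$early_tpr, early_fpr = x$early_fpr,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Plot a ROC curve
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy.roc_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f, pAUC(%g) = %.3f", object$auc, object$pauc_r, object$pauc)
    )
}
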