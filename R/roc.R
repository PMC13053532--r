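#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`, the quantity maximized to pick an
#' operating threshold on a ROC curve.
#'
#' @param sensitivity,specificity values in `[0, 1]`.
#' @return J in `[-1, 1]`.
#' @export
youden_j <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' ROC analysis with the Youden-optimal threshold
#'
#' The AUC is the rank (Mann-Whitney) probability that a positive case
#' outscores a negative one, with ties counted 1/2 (midranks). The score
#' orientation is chosen so that the positive class has the higher mean
#' score (`higher_is_positive`; ties default to that direction), and the
#' AUC is reported in that orientation. The operating threshold maximizes
#' Youden's J over the candidate set of midpoints between adjacent distinct
#' observed scores plus `-Inf`/`+Inf` sentinels; ties in J are broken
#' toward higher specificity. The threshold is reported with its direction:
#' a case is called positive when `score >= threshold`
#' (`higher_is_positive`) or `score <= threshold` (`lower_is_positive`).
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels; both classes must be
#'   present.
#' @return An object of class `roc_result`: `auc`, `direction`,
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`, `n_pos`,
#'   `n_neg`.
#' @export
roc_with_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("missing values in scores or labels", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  direction <- if (mean(scores[labels]) >= mean(scores[!labels]))
    "higher_is_positive" else "lower_is_positive"
  s <- if (direction == "higher_is_positive") scores else -scores

  # rank formulation with midranks
  r <- rank(s)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  cand <- sort(unique(s))
  cuts <- c(-Inf, if (length(cand) > 1) (cand[-1] + cand[-length(cand)]) / 2,
            Inf)
  best <- NULL
  for (cut in cuts) {
    sens <- mean(s[labels] >= cut)
    spec <- mean(s[!labels] < cut)
    j <- youden_j(sens, spec)
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(cut = cut, sens = sens, spec = spec, j = j)
  }
  thr <- if (direction == "higher_is_positive") best$cut else -best$cut
  structure(list(auc = auc, direction = direction, threshold = thr,
                 sensitivity = best$sens, specificity = best$spec,
                 youden_j = best$j, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  op <- if (x$direction == "higher_is_positive") ">=" else "<="
  cat(sprintf("<roc_result> AUC %.3f (%d pos / %d neg)\n  optimal threshold %s %.4g: sensitivity %.3f, specificity %.3f, Youden J %.3f\n",
              x$auc, x$n_pos, x$n_neg, op, x$threshold,
              x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}
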