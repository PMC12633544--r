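#' ROC and precision-recall analysis of an envelope against labels
#'
#' Threshold sweep over the distinct score values (classifying `score >=
#' threshold` as positive). ROC-AUC is computed by the trapezoid rule and
#' equals the Mann-Whitney pair statistic (ties counted 1/2); PR-AUC uses
#' step-wise interpolation (sum of precision x recall increments), avoiding
#' the optimism of trapezoidal PR interpolation.
#'
#' With no negative samples the ROC is undefined: `roc_auc` is `NA` with a
#' warning while the PR side degenerates to precision 1 everywhere
#' (`pr_auc = 1`). With no positive samples both curves are undefined and
#' an error is raised.
#'
#' @param scores numeric scores (an [envelope_signal()] or plain vector).
#' @param labels binary labels (0/1 or logical), one per score.
#' @return list with `roc` (`threshold`, `fpr`, `tpr`), `pr` (`threshold`,
#'   `recall`, `precision`), `roc_auc`, `pr_auc`.
#' @examples
#' roc_pr(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$roc_auc  # 0.75
#' @export
roc_pr <- function(scores, labels) {
  if (inherits(scores, "envelope_signal")) scores <- scores$values
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have equal length")
  }
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L) stop("ROC/PR undefined: no positive samples")

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # cumulative counts at the end of each tie group of distinct scores
  grp_end <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(l)[grp_end]
  fp <- (grp_end - cumsum(l)[grp_end])
  thr <- s[grp_end]
  tpr <- tp / P
  fpr <- if (N > 0L) fp / N else rep(NA_real_, length(fp))
  precision <- tp / (tp + fp)
  recall <- tpr

  if (N == 0L) {
    warning("no negative samples: ROC undefined, roc_auc = NA")
    roc_auc <- NA_real_
  } else {
    roc_auc <- sum(diff(c(0, fpr)) * (tpr + c(0, head(tpr, -1))) / 2)
  }
  pr_auc <- sum(diff(c(0, recall)) * precision)

  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = thr, recall = recall,
                       precision = precision),
       roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Event-level precision, recall and F1
#'
#' Matches LOW-to-HIGH detections against annotated events: a detection
#' matches an event if it falls within `[onset - tolerance, offset +
#' tolerance]`. Matching is one-to-one and greedy in time order (ties
#' broken by earliest detection). F1 is the harmonic mean of precision and
#' recall; with no true positives it is 0.
#'
#' @param state a `state_trace` (or numeric vector of detection times in
#'   seconds).
#' @param annotations data frame with `onset_s`, `offset_s`.
#' @param tolerance_s matching tolerance, seconds.
#' @return list `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
event_f1 <- function(state, annotations, tolerance_s = 0) {
  if (tolerance_s < 0) stop("'tolerance_s' must be non-negative")
  det <- if (inherits(state, "state_trace")) {
    state$transitions$time_s[state$transitions$direction == "low_to_high"]
  } else as.numeric(state)
  det <- sort(det)
  n_ev <- nrow(annotations)
  matched_ev <- rep(FALSE, n_ev)
  tp <- 0L
  ord <- if (n_ev) order(annotations$onset_s) else integer(0)
  for (t in det) {
    for (j in ord) {
      if (matched_ev[j]) next
      if (t >= annotations$onset_s[j] - tolerance_s &&
          t <= annotations$offset_s[j] + tolerance_s) {
        matched_ev[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  fp <- length(det) - tp
  fn <- n_ev - tp
  precision <- if (length(det)) tp / length(det) else 1
  recall <- if (n_ev) tp / n_ev else 1
  f1 <- if (tp > 0L) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Bias the operating point for day or night use
#'
#' Picks a threshold from a ROC curve according to the diurnal biasing
#' policy: in `day` mode, minimise the false-positive rate subject to a
#' minimum sensitivity (conservative daytime triggering); in `night` mode,
#' maximise sensitivity subject to a false-positive ceiling (aggressive
#' nighttime protection). The returned threshold is the midpoint of the
#' score gap realising the chosen point. If the constraint is infeasible
#' the nearest feasible point is returned with a warning.
#'
#' @param roc the `roc` data frame from [roc_pr()] (columns `threshold`,
#'   `fpr`, `tpr`, ordered by decreasing threshold).
#' @param mode `"day"` or `"night"`.
#' @param tpr_min day-mode sensitivity floor.
#' @param fpr_max night-mode false-positive ceiling.
#' @return the selected threshold (numeric scalar).
#' @export
bias_operating_point <- function(roc, mode = c("day", "night"),
                                 tpr_min = 0.8, fpr_max = 0.3) {
  mode <- match.arg(mode)
  if (!nrow(roc)) stop("empty ROC curve")
  if (any(is.na(roc$fpr))) stop("degenerate ROC curve (single-class labels)")
  if (mode == "day") {
    ok <- roc$tpr >= tpr_min
    if (!any(ok)) {
      warning("no point reaches tpr_min; returning the most sensitive point")
      k <- which.max(roc$tpr)
    } else {
      cand <- which(ok)
      k <- cand[which.min(roc$fpr[cand])]
    }
  } else {
    ok <- roc$fpr <= fpr_max
    if (!any(ok)) {
      warning("no point satisfies fpr_max; returning the most specific point")
      k <- which.min(roc$fpr)
    } else {
      cand <- which(ok)
      k <- cand[which.max(roc$tpr[cand])]
    }
  }
  # thresholds are distinct scores in decreasing order; any value in
  # (threshold[k+1], threshold[k]] realises point k — return the midpoint
  if (k < nrow(roc)) (roc$threshold[k] + roc$threshold[k + 1L]) / 2
  else roc$threshold[k]
}
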