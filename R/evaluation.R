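# Precision-recall machinery and the adjusted AUCPR metric.
#
# AUCPR alone is not comparable across effective-threshold choices: a more
# permissive h1 raises the positive-class prevalence, which raises the
# precision at full recall (P_R=1) and with it the whole curve's floor.
# AUCPR_adj = AUCPR - P_R=1 subtracts that prevalence floor, so a model with
# no discriminatory ability scores 0 at any prevalence and models labeled
# with different thresholds can be ranked on one scale.

#' Contingency table at a fixed margin
#'
#' @param y_true binary ground-truth labels (1 = effective).
#' @param y_pred binary predictions.
#' @return object of class `contingency_table` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
contingency_table <- function(y_true, y_pred) {
  yt <- as_positive(y_true)
  yp <- as_positive(y_pred)
  if (length(yt) != length(yp)) stop("y_true and y_pred lengths differ")
  if (length(yt) < 1L) stop("need at least one record")
  structure(list(tp = sum(yt & yp), fp = sum(!yt & yp),
                 tn = sum(!yt & !yp), fn = sum(yt & !yp)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency table: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Precision-recall curve over all confidence margins
#'
#' One point per distinct score value used as margin (prediction positive iff
#' score strictly exceeds the margin, matching [classify()]), in descending
#' margin order, plus the full-recall endpoint (margin `-Inf`) where every
#' record is predicted positive and precision equals the positive prevalence.
#' Precision with zero predicted positives is defined as 1, giving a
#' well-formed left endpoint.
#'
#' @param y_true binary labels with at least one positive.
#' @param scores numeric confidence scores.
#' @return object of class `pr_curve`: data frame with columns `margin`,
#'   `recall`, `precision` and attributes `n_pos`, `n_neg`.
#' @export
precision_recall_curve <- function(y_true, scores) {
  yt <- as_positive(y_true)
  if (length(yt) != length(scores)) stop("y_true and scores lengths differ")
  n_pos <- sum(yt)
  n_neg <- sum(!yt)
  if (n_pos == 0L) stop("recall is undefined without at least one positive record")
  margins <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  recall <- precision <- numeric(length(margins))
  for (i in seq_along(margins)) {
    pred <- scores > margins[i]
    tp <- sum(pred & yt)
    fp <- sum(pred & !yt)
    precision[i] <- if (tp + fp == 0L) 1 else tp / (tp + fp)
    recall[i] <- tp / n_pos
  }
  curve <- data.frame(margin = margins, recall = recall, precision = precision)
  attr(curve, "n_pos") <- n_pos
  attr(curve, "n_neg") <- n_neg
  class(curve) <- c("pr_curve", "data.frame")
  curve
}

#' Area under a precision-recall curve
#'
#' Step integration over recall: with curve points ordered by non-decreasing
#' recall, `AUCPR = sum_i (r_i - r_{i-1}) * p_i` (r_0 = 0). Each precision is
#' attributed to the recall increment that reaches its point, the standard
#' average-precision step rule; it avoids the optimism of linear PR
#' interpolation and makes an uninformative ranker's area equal the
#' prevalence exactly.
#'
#' @param curve a `pr_curve`.
#' @return area in `[0, 1]`.
#' @export
aucpr <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Precision at full recall (positive prevalence)
#'
#' The precision of predicting every record positive: `n_pos / n`. This is
#' the right endpoint of the precision-recall curve and the prevalence floor
#' subtracted by [aucpr_adj()].
#'
#' @param y_true binary labels with at least one positive.
#' @return prevalence in `(0, 1]`.
#' @export
p_at_full_recall <- function(y_true) {
  yt <- as_positive(y_true)
  if (!any(yt)) stop("undefined without at least one positive record")
  mean(yt)
}

#' Prevalence-adjusted area under the precision-recall curve
#'
#' `AUCPR_adj = AUCPR - P_R=1`. Zero for a model with no discriminatory
#' ability, `1 - prevalence` for a perfect ranker, and possibly negative for
#' worse-than-baseline rankers. Unlike raw AUCPR it is comparable across
#' labelings with different effective-class prevalences.
#'
#' @param curve a `pr_curve`.
#' @param y_true binary labels the curve was computed from; if omitted, the
#'   prevalence is taken from the curve's `n_pos`/`n_neg` attributes.
#' @return adjusted area.
#' @export
aucpr_adj <- function(curve, y_true = NULL) {
  stopifnot(inherits(curve, "pr_curve"))
  p_r1 <- if (is.null(y_true)) {
    attr(curve, "n_pos") / (attr(curve, "n_pos") + attr(curve, "n_neg"))
  } else {
    p_at_full_recall(y_true)
  }
  aucpr(curve) - p_r1
}

#' Min-max normalize a collection of metric values to 0-100
#'
#' Applied once per evaluation stage (e.g. all cross-validation AUCPR_adj
#' values together, all holdout values together) so models are compared on a
#' common 0-100 scale within a stage. A constant collection maps to all 0.
#'
#' @param values numeric vector.
#' @return values rescaled to `[0, 100]`.
#' @export
normalize_scores <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  rng <- range(values)
  if (diff(rng) == 0) return(rep(0, length(values)))
  (values - rng[1]) / diff(rng) * 100
}

#' Area under the ROC curve
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, ties counted half (rank/Mann-Whitney formulation). Reported for
#' comparison with AUCPR_adj; ROC AUC overestimates performance on
#' imbalanced labelings.
#'
#' @param y_true binary labels with both classes present.
#' @param scores numeric confidence scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  yt <- as_positive(y_true)
  if (length(yt) != length(scores)) stop("y_true and scores lengths differ")
  n_pos <- sum(yt); n_neg <- sum(!yt)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC AUC is undefined unless both classes are present")
  }
  r <- rank(scores)
  (sum(r[yt]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Vertically average precision-recall curves
#'
#' Evaluates each curve's precision on a shared recall grid (0 to 1, 101
#' points) by step interpolation (precision of the first curve point whose
#' recall reaches the grid value, consistent with the [aucpr()] step rule)
#' and averages pointwise. Used to pool the K cross-validation rounds into a
#' single curve.
#'
#' @param curves non-empty list of `pr_curve` objects.
#' @param grid_points number of grid points (default 101).
#' @return a `pr_curve` on the shared recall grid (margins are `NA`;
#'   `n_pos`/`n_neg` attributes are the means over the input curves).
#' @export
average_pr_curves <- function(curves, grid_points = 101L) {
  if (!is.list(curves) || length(curves) == 0L ||
      !all(vapply(curves, inherits, logical(1), "pr_curve"))) {
    stop("curves must be a non-empty list of pr_curve objects")
  }
  grid <- seq(0, 1, length.out = grid_points)
  prec <- vapply(curves, function(cv) {
    interp_precision(cv$recall, cv$precision, grid)
  }, numeric(grid_points))
  avg <- data.frame(margin = NA_real_, recall = grid,
                    precision = rowMeans(matrix(prec, nrow = grid_points)))
  attr(avg, "n_pos") <- mean(vapply(curves, attr, numeric(1), "n_pos"))
  attr(avg, "n_neg") <- mean(vapply(curves, attr, numeric(1), "n_neg"))
  class(avg) <- c("pr_curve", "data.frame")
  avg
}

# Step interpolation: precision at recall r is the precision of the first
# curve point (in non-decreasing recall order) with recall >= r.
interp_precision <- function(recall, precision, grid) {
  vapply(grid, function(r) {
    i <- which(recall >= r - 1e-12)[1]
    if (is.na(i)) precision[length(precision)] else precision[i]
  }, numeric(1))
}

#' Full evaluation of a trained classifier on a labeled set
#'
#' Computes the precision-recall curve, AUCPR, P_R=1, AUCPR_adj, ROC AUC and
#' the contingency table at the given margin.
#'
#' @param model a `trained_classifier`.
#' @param X feature matrix of the evaluation records.
#' @param y_true binary labels (1 = effective), both classes present.
#' @param margin confidence margin for the contingency table (default 0.5).
#' @return object of class `model_evaluation` with fields `curve`, `aucpr`,
#'   `p_r1`, `aucpr_adj`, `roc_auc`, `table`, `normalized_adj` (`NA` until a
#'   cross-model normalization stage fills it).
#' @export
evaluate_classifier <- function(model, X, y_true, margin = 0.5) {
  scores <- predict_confidence(model, X)
  yt <- as_positive(y_true)
  curve <- precision_recall_curve(yt, scores)
  a <- aucpr(curve)
  p1 <- p_at_full_recall(yt)
  roc <- if (any(yt) && !all(yt)) roc_auc(yt, scores) else NA_real_
  structure(list(curve = curve, aucpr = a, p_r1 = p1, aucpr_adj = a - p1,
                 roc_auc = roc,
                 table = contingency_table(yt, classify(scores, margin)),
                 margin = margin, normalized_adj = NA_real_),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("model evaluation: AUCPR=%.4f P_R=1=%.4f AUCPR_adj=%.4f ROC AUC=%s\n",
              x$aucpr, x$p_r1, x$aucpr_adj,
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.4f", x$roc_auc))))
  print(x$table)
  invisible(x)
}

#' Export a precision-recall curve as TSV
#'
#' @param curve a `pr_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pr_curve <- function(curve, path) {
  stopifnot(inherits(curve, "pr_curve"))
  utils::write.table(as.data.frame(curve)[c("margin", "recall", "precision")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
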