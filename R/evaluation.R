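#' Confusion-count report at a fixed probability cutoff
#'
#' Decisions are `score >= threshold` for the positive class (OA). Counts,
#' per-class and overall percent-correct are reported, percentages rounded
#' to two decimals.
#'
#' @param y_true True labels (`"HC"` / `"OA"` or a 2-level factor; the
#'   second level is the positive class).
#' @param scores Positive-class probabilities.
#' @param threshold Decision cutoff.
#' @return An object of class `evaluation_report` containing the counts
#'   table and overall accuracy.
#' @export
confusion_report <- function(y_true, scores, threshold = 0.5) {
  y <- factor(y_true)
  if (nlevels(y) > 2L) stop("binary labels expected")
  lev <- levels(y)
  pos <- lev[length(lev)]
  pred <- ifelse(scores >= threshold, pos, lev[1L])
  counts <- do.call(rbind, lapply(lev, function(cl) {
    tot <- sum(y == cl)
    cor <- sum(y == cl & pred == cl)
    data.frame(class = cl, total = tot, correct = cor,
               incorrect = tot - cor,
               correct_pct = round(100 * cor / tot, 2),
               incorrect_pct = round(100 * (tot - cor) / tot, 2),
               stringsAsFactors = FALSE)
  }))
  overall <- data.frame(class = "Total", total = length(y),
                        correct = sum(pred == as.character(y)),
                        incorrect = sum(pred != as.character(y)),
                        correct_pct = round(100 * mean(pred == as.character(y)), 2),
                        incorrect_pct = round(100 * mean(pred != as.character(y)), 2),
                        stringsAsFactors = FALSE)
  structure(list(counts = rbind(counts, overall), threshold = threshold,
                 overall_accuracy = overall$correct_pct),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> threshold=%.3f  overall %.2f%% correct\n",
              x$threshold, x$overall_accuracy))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' ROC curve points
#'
#' One (false-positive rate, true-positive rate) point per distinct score
#' cutoff (ties grouped), plus the trivial (0,0) and (1,1) endpoints.
#'
#' @inheritParams confusion_report
#' @return A data.frame with columns `fpr`, `tpr`, `cutoff` (the cutoff
#'   achieving each point; `Inf`/`-Inf` for the endpoints), monotone
#'   non-decreasing in both coordinates.
#' @export
roc_curve <- function(y_true, scores) {
  y <- factor(y_true)
  lev <- levels(y)
  pos <- lev[length(lev)]
  is_pos <- y == pos
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(ct) sum(scores >= ct & is_pos) / n_pos,
                numeric(1))
  fpr <- vapply(cuts, function(ct) sum(scores >= ct & !is_pos) / n_neg,
                numeric(1))
  df <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                   cutoff = c(Inf, cuts, -Inf))
  df[!duplicated(df[, c("fpr", "tpr")]), , drop = FALSE]
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the ROC points; algebraically identical to the
#' tie-corrected probability that a random positive scores above a random
#' negative (ties counted half).
#'
#' @param roc Output of [roc_curve()], or `y_true` when `scores` is given.
#' @param scores Optional; compute the curve internally.
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(roc, scores = NULL) {
  if (!is.null(scores)) roc <- roc_curve(roc, scores)
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' ROC-optimal operating threshold (Youden's J)
#'
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' scores (plus just-outside-the-extremes cutoffs); the cutoff maximising
#' `J = TPR - FPR` is returned, ties going to the lower cutoff. With
#' perfectly separating scores this is the midpoint of the gap between the
#' classes.
#'
#' @inheritParams confusion_report
#' @return Scalar cutoff.
#' @export
roc_threshold <- function(y_true, scores) {
  y <- factor(y_true)
  lev <- levels(y)
  pos <- lev[length(lev)]
  is_pos <- y == pos
  s <- sort(unique(scores))
  if (length(s) == 1L) {
    warning("all scores are identical; returning that score")
    return(s)
  }
  cand <- (head(s, -1) + s[-1]) / 2
  cand <- c(s[1L] - (s[2L] - s[1L]) / 2, cand,
            s[length(s)] + (s[length(s)] - s[length(s) - 1L]) / 2)
  j <- vapply(cand, function(ct) {
    sum(scores >= ct & is_pos) / sum(is_pos) -
      sum(scores >= ct & !is_pos) / sum(!is_pos)
  }, numeric(1))
  cand[which(j == max(j))[1L]]   # ties -> lower cutoff
}

#' Full evaluation bundle for one classifier on one partition
#'
#' @param clf A trained `vag_classifier`.
#' @param X,y Inputs and labels of the partition.
#' @param threshold Decision cutoff for the confusion counts.
#' @return A list: `report` (confusion), `roc` (curve points), `auroc`,
#'   `roc_threshold`.
#' @export
evaluate_classifier <- function(clf, X, y, threshold = 0.5) {
  P <- predict(clf, as.matrix(X))
  scores <- P[, 2L]
  roc <- roc_curve(y, scores)
  list(report = confusion_report(y, scores, threshold),
       roc = roc, auroc = auroc(roc),
       roc_threshold = roc_threshold(y, scores))
}
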