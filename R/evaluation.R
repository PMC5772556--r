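# Confusion-matrix metrics and ROC/AUC with repressor as the positive class.

computeMetrics <- function(tp, fp, tn, fn, positive = "repressor") {
  n <- tp + fp + tn + fn
  acc <- if (n > 0) (tp + tn) / n else NA_real_
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  spe <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  new("ConfusionMetrics", tp = tp, fp = fp, tn = tn, fn = fn,
      acc = acc, sen = sen, spe = spe, mcc = mcc, positive = positive)
}

#' Confusion-matrix metrics for role predictions
#'
#' Repressor sites are the positive class: TP counts repressors predicted as
#' repressors, TN activators predicted as activators. Derived metrics are
#' ACC = (TP+TN)/n, SEN = TP/(TP+FN), SPE = TN/(TN+FP) and the Matthews
#' correlation coefficient, defined as 0 when its denominator vanishes
#' (e.g. an all-activator prediction).
#'
#' @param truth,pred equal-length role vectors over
#'   \{`activator`, `repressor`\}.
#' @param positive positive class label, default `"repressor"`.
#' @return a [ConfusionMetrics-class].
#' @export
confusionMetrics <- function(truth, pred, positive = "repressor") {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  pos <- truth == positive
  predPos <- pred == positive
  computeMetrics(tp = sum(pos & predPos), fp = sum(!pos & predPos),
                 tn = sum(!pos & !predPos), fn = sum(pos & !predPos),
                 positive = positive)
}

#' Reconstruct confusion metrics from class sizes and printed SEN/SPE
#'
#' Given the positive/negative class sizes and sensitivity/specificity
#' reported at two decimals, rebuilds the integer confusion matrix
#' (`TP = round(sen * nPos)`, `TN = round(spe * nNeg)`) and recomputes ACC
#' and MCC — the worked-example check that rounded published metrics are
#' mutually consistent.
#'
#' @param nPos,nNeg class sizes (positive = repressor).
#' @param sen,spe printed sensitivity and specificity.
#' @return a [ConfusionMetrics-class].
#' @export
reconstructConfusion <- function(nPos, nNeg, sen, spe) {
  tp <- round(sen * nPos)
  tn <- round(spe * nNeg)
  computeMetrics(tp = tp, fp = nNeg - tn, tn = tn, fn = nPos - tp)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps thresholds over the unique score values (ties grouped, so tied
#' positives and negatives advance the curve diagonally) and integrates by
#' the trapezoid rule; the resulting AUC equals the rank-sum
#' (Mann-Whitney) probability that a random positive outscores a random
#' negative, with ties counted half. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric decision values, larger = more positive-like.
#' @param truth role labels.
#' @param positive positive class, default `"repressor"`.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
rocAuc <- function(scores, truth, positive = "repressor") {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) {
    stop("ROC needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  uniq <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(p)[uniq]
  fp <- cumsum(!p)[uniq]
  pts <- data.frame(fpr = c(0, fp / nN), tpr = c(0, tp / nP),
                    threshold = c(Inf, s[uniq]))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Write ROC points as TSV
#'
#' @param roc result of [rocAuc()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRocPoints <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
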