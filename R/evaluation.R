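#' Classification metrics from confusion counts
#'
#' Sensitivity Sn = TP / (TP + FN), specificity Sp = TN / (TN + FP),
#' accuracy Acc = (TP + TN) / (TP + TN + FP + FN) and the Matthews
#' correlation coefficient with the standard denominator
#' sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)); a zero denominator yields MCC = 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Named list with \code{Sn}, \code{Sp}, \code{Acc}, \code{MCC}.
#' @examples
#' compute_metrics(50, 100, 0, 0)$MCC  # 1
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  if (min(tp, tn, fp, fn) < 0) stop("counts must be non-negative", call. = FALSE)
  pos <- tp + fn
  neg <- tn + fp
  if (pos + neg == 0) stop("empty confusion table", call. = FALSE)
  sn <- if (pos > 0) tp / pos else NA_real_
  sp <- if (neg > 0) tn / neg else NA_real_
  acc <- (tp + tn) / (pos + neg)
  denom <- sqrt(pos) * sqrt(neg) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc)
}

# Confusion counts from predicted and true labels ("positive"/"negative").
confusion_counts <- function(predicted, truth) {
  list(tp = sum(predicted == "positive" & truth == "positive"),
       tn = sum(predicted == "negative" & truth == "negative"),
       fp = sum(predicted == "positive" & truth == "negative"),
       fn = sum(predicted == "negative" & truth == "positive"))
}

#' ROC curve and AUC of a scored classification
#'
#' AUC by the rank (Mann-Whitney) method, ties counting one half; the ROC
#' points are the (FPR, TPR) pairs obtained by sweeping the decision
#' threshold over the distinct scores.
#'
#' @param scores Numeric decision scores (larger = more positive-like).
#' @param labels Character labels \code{"positive"}/\code{"negative"}.
#' @return List with \code{auc} and \code{points} (data frame of
#'   \code{fpr}, \code{tpr} from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("ROC needs both classes present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie block
  tpr <- cumsum(p)[keep] / n1
  fpr <- cumsum(!p)[keep] / n0
  list(auc = auc,
       points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Pooled stratified k-fold cross-validation
#'
#' Splits positives and negatives separately into k near-equal folds, fits
#' the model on each training split, scores the held-out fold, and computes
#' one metric set from the pooled out-of-fold predictions (micro-averaging,
#' not a per-fold mean).
#'
#' @param positive_windows,negative_windows Fragment windows.
#' @param fit_fun Function \code{(positive_windows, negative_windows) ->
#'   model}.
#' @param score_fun Function \code{(model, windows) -> data.frame(score,
#'   label)}; the default calls \code{predict}.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with \code{metrics} (Sn/Sp/Acc/MCC), \code{auc},
#'   \code{counts} and the pooled \code{predictions} data frame.
#' @export
cross_validate <- function(positive_windows, negative_windows, fit_fun,
                           score_fun = function(model, w) predict(model, w),
                           k = 5L, seed = 1L) {
  windows <- c(positive_windows, negative_windows)
  truth <- rep(c("positive", "negative"),
               c(length(positive_windows), length(negative_windows)))
  fold <- stratified_folds(truth, k, seed)
  pred <- data.frame(score = numeric(length(windows)),
                     label = character(length(windows)),
                     stringsAsFactors = FALSE)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_fun(windows[tr & truth == "positive"],
                     windows[tr & truth == "negative"])
    out <- score_fun(model, windows[!tr])
    pred$score[!tr] <- out$score
    pred$label[!tr] <- out$label
  }
  cc <- confusion_counts(pred$label, truth)
  roc <- roc_auc(pred$score, truth)
  list(metrics = compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn),
       auc = roc$auc, counts = cc,
       predictions = cbind(pred, truth = truth, fold = fold))
}

#' Cross-validation under repeated negative resampling
#'
#' Repeats the full cross-validation with a fresh 1:ratio negative sample
#' drawn from the pool on every repeat (30 repeats by default) and reports
#' the per-repeat and mean metrics, smoothing out the arbitrariness of any
#' single negative draw.
#'
#' @param positive_windows Positive fragment windows.
#' @param negative_pool Full negative pool to sample from.
#' @param fit_fun,score_fun,k As in \code{\link{cross_validate}}.
#' @param repeats Number of resampling repeats (default 30).
#' @param ratio Negative:positive ratio of each sample (default 2).
#' @param seed Base seed; repeat r uses \code{seed + r} for its draw and
#'   fold assignment.
#' @return List with \code{mean} (mean Sn/Sp/Acc/MCC/AUC) and
#'   \code{per_repeat} (data frame, one row per repeat).
#' @export
repeated_resampling_eval <- function(positive_windows, negative_pool,
                                     fit_fun,
                                     score_fun = function(model, w)
                                       predict(model, w),
                                     repeats = 30L, ratio = 2L, k = 5L,
                                     seed = 1L) {
  need <- ratio * length(positive_windows)
  if (length(negative_pool) < need)
    stop(sprintf("negative pool too small: need %d, have %d",
                 need, length(negative_pool)), call. = FALSE)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    idx <- local({
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed + r)
      sample.int(length(negative_pool), need)
    })
    cv <- cross_validate(positive_windows, negative_pool[idx], fit_fun,
                         score_fun, k, seed + r)
    rows[[r]] <- data.frame(repeat_id = r, Sn = cv$metrics$Sn,
                            Sp = cv$metrics$Sp, Acc = cv$metrics$Acc,
                            MCC = cv$metrics$MCC, AUC = cv$auc)
  }
  tab <- do.call(rbind, rows)
  list(mean = as.list(colMeans(tab[, -1L])), per_repeat = tab)
}

#' Evaluate a fitted model on an independent test set
#'
#' Single-pass evaluation on fragments that must be blind to training:
#' if training site keys are supplied, any overlap between training and
#' test sites is an error naming the offending sites.
#'
#' @param model Fitted model with a \code{predict} method returning
#'   \code{data.frame(score, label)} for a vector of windows.
#' @param test_positive,test_negative Test fragment windows.
#' @param train_keys Optional character keys (e.g.
#'   \code{"protein position"}) of the training sites.
#' @param test_keys Optional keys of the test sites, positives first.
#' @param score_fun Scoring function, as in \code{\link{cross_validate}}.
#' @return List with \code{metrics}, \code{auc} and \code{counts}.
#' @export
independent_test <- function(model, test_positive, test_negative,
                             train_keys = NULL, test_keys = NULL,
                             score_fun = function(model, w)
                               predict(model, w)) {
  if (!is.null(train_keys) && !is.null(test_keys)) {
    overlap <- intersect(train_keys, test_keys)
    if (length(overlap))
      stop("test set overlaps training sites: ",
           paste(utils::head(overlap, 5L), collapse = ", "),
           if (length(overlap) > 5L) ", ...", call. = FALSE)
  }
  truth <- rep(c("positive", "negative"),
               c(length(test_positive), length(test_negative)))
  out <- score_fun(model, c(test_positive, test_negative))
  cc <- confusion_counts(out$label, truth)
  roc <- roc_auc(out$score, truth)
  list(metrics = compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn),
       auc = roc$auc, counts = cc)
}
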