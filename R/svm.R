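#' Bit-score feature vectors over a set of subgroup profiles
#'
#' One column per profile, in the fixed order the profiles were trained in;
#' this is the feature representation consumed by the second-layer SVM.
#'
#' @param profiles List of \code{profile_model}s.
#' @param windows Character vector of site windows.
#' @return Numeric matrix, one row per window, columns named by subgroup id.
#' @export
bitscore_vector <- function(profiles, windows) {
  out <- vapply(profiles, function(p) bit_score(p, windows),
                numeric(length(windows)))
  if (length(windows) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- vapply(profiles, `[[`, character(1), "subgroup_id")
  out
}

# Per-dimension affine map of training min/max to [-1, 1]; constant
# dimensions map to 0.
fit_scaler <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  list(lo = lo, hi = hi)
}

apply_scaler <- function(scaler, x) {
  span <- scaler$hi - scaler$lo
  span[span == 0] <- 1
  out <- sweep(x, 2L, scaler$lo)
  out <- sweep(out, 2L, span, "/") * 2 - 1
  out[, scaler$hi == scaler$lo] <- 0
  out
}

#' Default RBF-SVM hyperparameter grid
#'
#' Log2 grids over cost and kernel width: cost 2^-5..2^15 and gamma
#' 2^-15..2^3, both in steps of 2^2 — the conventional coarse grid of the
#' libsvm tuning script.
#'
#' @return List with numeric \code{cost} and \code{gamma} vectors.
#' @export
default_svm_grid <- function() {
  list(cost = 2^seq(-5L, 15L, by = 2L), gamma = 2^seq(-15L, 3L, by = 2L))
}

# Stratified fold assignment: within each class, fold sizes differ by at
# most one. Returns an integer vector of fold ids.
stratified_folds <- function(labels, k, seed) {
  if (any(table(labels) < k))
    stop(sprintf("cannot make %d folds: smallest class has %d members",
                 k, min(table(labels))), call. = FALSE)
  fold <- integer(length(labels))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train an RBF-SVM with grid-searched hyperparameters
#'
#' Scales every feature dimension to [-1, 1] by its training range, selects
#' cost and gamma by stratified internal cross-validated accuracy over the
#' grid (ties broken by smaller cost, then smaller gamma), and refits on all
#' data. Decision values are oriented so that larger means more
#' positive-like.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels, coerced to factor with levels negative/positive.
#' @param grid Hyperparameter grid (see \code{\link{default_svm_grid}}).
#' @param folds Internal CV folds for the grid search (default 5).
#' @param seed Seed controlling the fold assignment.
#' @return A \code{carb_svm}: scaler, fitted \code{e1071::svm} object,
#'   chosen hyperparameters and their CV accuracy.
#' @export
train_rbf_svm <- function(x, y, grid = default_svm_grid(), folds = 5L,
                          seed = 1L) {
  y <- factor(as.character(y), levels = c("negative", "positive"))
  if (anyNA(y)) stop("labels must be 'positive'/'negative'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  fold <- stratified_folds(as.character(y), folds, seed)

  best <- NULL
  for (cost in grid$cost) for (gamma in grid$gamma) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], scale = FALSE,
                        kernel = "radial", cost = cost, gamma = gamma)
      pred <- stats::predict(fit, xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc <- correct / length(y)
    if (is.null(best) || acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 &&
         (cost < best$cost || (cost == best$cost && gamma < best$gamma)))) {
      best <- list(cost = cost, gamma = gamma, acc = acc)
    }
  }

  fit <- e1071::svm(xs, y, scale = FALSE, kernel = "radial",
                    cost = best$cost, gamma = best$gamma)
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1L]
  orientation <- if (mean(dv[y == "positive"]) >= mean(dv[y == "negative"]))
    1 else -1
  structure(list(scaler = scaler, fit = fit, cost = best$cost,
                 gamma = best$gamma, cv_accuracy = best$acc,
                 orientation = orientation),
            class = "carb_svm")
}

#' @export
predict.carb_svm <- function(object, newdata, ...) {
  xs <- apply_scaler(object$scaler, newdata)
  pred <- stats::predict(object$fit, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1L] * object$orientation
  data.frame(score = as.numeric(dv), label = as.character(pred),
             stringsAsFactors = FALSE)
}

#' Train a single-feature-scheme SVM baseline
#'
#' Encodes the fragments under one of the six feature schemes and trains the
#' same grid-searched RBF-SVM used by the second layer; used for
#' feature-comparison baselines.
#'
#' @param positive_windows,negative_windows Training fragments.
#' @param scheme Encoding scheme (see \code{\link{encode_fragments}}).
#' @param grid,folds,seed As in \code{\link{train_rbf_svm}}.
#' @param pwm_windows Windows used to build the PWM for scheme
#'   \code{"pwm"}; defaults to \code{positive_windows}.
#' @return A \code{feature_svm}: the fitted \code{carb_svm} plus the scheme
#'   and any scheme state (the PWM) needed to encode new fragments.
#' @export
train_single_feature_svm <- function(positive_windows, negative_windows,
                                     scheme = "aac",
                                     grid = default_svm_grid(), folds = 5L,
                                     seed = 1L, pwm_windows = NULL) {
  pwm <- NULL
  if (scheme == "pwm")
    pwm <- build_pwm(if (is.null(pwm_windows)) positive_windows else pwm_windows)
  windows <- c(positive_windows, negative_windows)
  x <- encode_fragments(windows, scheme, pwm = pwm)
  y <- rep(c("positive", "negative"),
           c(length(positive_windows), length(negative_windows)))
  svm <- train_rbf_svm(x, y, grid, folds, seed)
  structure(list(svm = svm, scheme = scheme, pwm = pwm),
            class = "feature_svm")
}

#' @export
predict.feature_svm <- function(object, newdata, ...) {
  x <- encode_fragments(newdata, object$scheme, pwm = object$pwm)
  predict(object$svm, x)
}
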