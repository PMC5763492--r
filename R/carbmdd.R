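#' Control parameters for the two-layer site predictor
#'
#' Collects every tunable of the pipeline with its default: window
#' half-width 10 (21-mer fragments), 50% redundancy identity cut-off, 2:1
#' negative sampling, 30 resampling repeats, chi-squared significance
#' cut-off 34.3 (16 df, p = 0.005), maximum-cluster-size 30, pseudocount
#' 0.5 over a uniform background, and the conventional coarse libsvm
#' hyperparameter grid with 5 internal CV folds.
#'
#' @param n Window half-width.
#' @param identity_threshold Redundancy-reduction identity fraction.
#' @param neg_ratio Negative:positive sampling ratio.
#' @param repeats Negative-resampling repeats for evaluation.
#' @param chi2_threshold Positional-dependence significance cut-off.
#' @param max_cluster_size Minimum subgroup size eligible for splitting.
#' @param group_map Amino-acid group map for the chi-squared test.
#' @param pseudocount Profile-model pseudocount.
#' @param background Profile background: probabilities or a name understood
#'   by \code{\link{background_probs}}.
#' @param svm_grid Cost/gamma grid for the second-layer SVM.
#' @param cv_folds Folds for grid search and cross-validation.
#' @param criterion MDD split-position criterion (\code{"pair"}/\code{"sum"}).
#' @return A \code{carb_control} list.
#' @export
carb_control <- function(n = 10L, identity_threshold = 0.5, neg_ratio = 2L,
                         repeats = 30L, chi2_threshold = 34.3,
                         max_cluster_size = 30L,
                         group_map = default_group_map(),
                         pseudocount = 0.5, background = "uniform",
                         svm_grid = default_svm_grid(), cv_folds = 5L,
                         criterion = "pair") {
  structure(list(n = as.integer(n),
                 identity_threshold = identity_threshold,
                 neg_ratio = as.integer(neg_ratio),
                 repeats = as.integer(repeats),
                 chi2_threshold = chi2_threshold,
                 max_cluster_size = as.integer(max_cluster_size),
                 group_map = group_map, pseudocount = pseudocount,
                 background = background, svm_grid = svm_grid,
                 cv_folds = as.integer(cv_folds), criterion = criterion),
            class = "carb_control")
}

# One global seed expanded into fixed per-stage seeds (kept within the
# 32-bit integer range).
stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 100000L
  c(sampling = base * 10L + 1L, svm = base * 10L + 2L,
    eval = base * 10L + 3L)
}

#' Fit the two-layer carbonylation-site model
#'
#' End-to-end fit for one residue type: window extraction, redundancy
#' reduction (negatives also screened against the positives), 1:ratio
#' negative sampling, maximal-dependence-decomposition clustering of the
#' positives into motif subgroups, one bit-score profile per subgroup with
#' a balanced threshold, and a second-layer RBF-SVM over the subgroup
#' bit-score vectors.
#'
#' @param x Either a named character vector of protein sequences (with
#'   \code{sites}) or a prebuilt \code{carb_dataset}.
#' @param sites Positive-site annotation data frame (ignored when \code{x}
#'   is already a dataset).
#' @param residue Site residue type (K, R, T or P).
#' @param control A \code{\link{carb_control}}.
#' @param seed Integer seed governing every random stage.
#' @return A fitted \code{carbmdd} object.
#' @examples
#' syn <- synth_proteins(n_proteins = 12, n_positive_sites = 60, seed = 7)
#' fit <- carb_mdd(syn$proteins, syn$sites, "K",
#'                 control = carb_control(svm_grid = list(cost = 2^(0:2),
#'                                                        gamma = 2^(-3:-1))))
#' fit
#' @export
carb_mdd <- function(x, sites = NULL, residue = "K",
                     control = carb_control(), seed = 1L) {
  residue <- match.arg(residue, SITE_RESIDUES)
  seeds <- stage_seeds(seed)

  dataset <- if (inherits(x, "carb_dataset")) x
  else build_candidate_sites(x, sites, residue, control$n)

  n_pos_raw <- nrow(dataset$positives)
  n_neg_raw <- nrow(dataset$negatives)

  dataset$positives <- reduce_redundancy(dataset$positives,
                                         control$identity_threshold)
  dataset$negatives <- reduce_redundancy(dataset$negatives,
                                         control$identity_threshold,
                                         reference = dataset$positives$window)
  n_pos <- nrow(dataset$positives)
  if (!n_pos) stop("no positive fragments left after filtering", call. = FALSE)
  dataset <- sample_negatives(dataset, control$neg_ratio, seeds[["sampling"]])

  tree <- mdd_cluster(dataset$positives$window, control$group_map,
                      control$chi2_threshold, control$max_cluster_size,
                      control$criterion,
                      leaf_prefix = paste0("Carb", residue))

  bg <- background_probs(control$background)
  profiles <- lapply(tree$leaves, function(leaf) {
    m <- train_profile(tree$windows[leaf$members], control$pseudocount, bg,
                       subgroup_id = leaf$id)
    calibrate_threshold(m, tree$windows[leaf$members],
                        dataset$negatives$window)
  })

  train_windows <- c(dataset$positives$window, dataset$negatives$window)
  train_labels <- rep(c("positive", "negative"),
                      c(nrow(dataset$positives), nrow(dataset$negatives)))
  scores <- bitscore_vector(profiles, train_windows)
  # Stacking correction: a positive's score on its own subgroup profile is
  # resubstitution-biased (it contributed to those emissions), which would
  # push the second-layer boundary too high for unseen fragments. Replace
  # those entries with out-of-fold scores from profiles refit without the
  # fragment's fold.
  scores <- stack_positive_scores(scores, tree, control, bg,
                                  seeds[["svm"]])
  svm <- train_rbf_svm(scores, train_labels, control$svm_grid,
                       control$cv_folds, seeds[["svm"]])

  fit <- structure(list(residue = residue, tree = tree,
                        profiles = profiles, svm = svm,
                        dataset = dataset, control = control, seed = seed),
                   class = "carbmdd")
  fit$manifest <- build_manifest(fit, n_pos_raw, n_neg_raw)
  fit
}

# Out-of-fold bit scores of each leaf's own members: within every leaf the
# members are split into up to cv_folds folds and each fold is scored by a
# profile trained on the remaining members (single-member leaves keep the
# full-profile score). Other columns are unbiased and left untouched.
stack_positive_scores <- function(scores, tree, control, bg, seed) {
  for (li in seq_along(tree$leaves)) {
    mem <- tree$leaves[[li]]$members   # indices into the positive block
    size <- length(mem)
    if (size < 2L) next
    k <- min(control$cv_folds, size)
    fold <- with_seed(seed + li, sample(rep_len(seq_len(k), size)))
    for (f in seq_len(k)) {
      held <- mem[fold == f]
      rest <- mem[fold != f]
      if (!length(rest)) next
      sub <- train_profile(tree$windows[rest], control$pseudocount, bg,
                           subgroup_id = tree$leaves[[li]]$id)
      scores[held, li] <- bit_score(sub, tree$windows[held])
    }
  }
  scores
}

build_manifest <- function(fit, n_pos_raw, n_neg_raw) {
  ctrl <- fit$control
  leaves <- lapply(fit$tree$leaves, function(l)
    list(id = l$id, size = length(l$members)))
  manifest <- list(
    residue = fit$residue,
    seed = fit$seed,
    config = list(n = ctrl$n, identity_threshold = ctrl$identity_threshold,
                  neg_ratio = ctrl$neg_ratio,
                  chi2_threshold = ctrl$chi2_threshold,
                  max_cluster_size = ctrl$max_cluster_size,
                  pseudocount = ctrl$pseudocount,
                  criterion = ctrl$criterion,
                  cv_folds = ctrl$cv_folds,
                  group_map = as.list(stats::setNames(
                    as.integer(ctrl$group_map[AA20]), AA20))),
    counts = list(candidates_positive = n_pos_raw,
                  candidates_negative = n_neg_raw,
                  trained_positive = nrow(fit$dataset$positives),
                  trained_negative = nrow(fit$dataset$negatives)),
    subgroups = leaves,
    profile_thresholds = lapply(fit$profiles, function(p)
      list(id = p$subgroup_id, bit_threshold = p$bit_threshold)),
    svm = list(cost = fit$svm$cost, gamma = fit$svm$gamma,
               cv_accuracy = fit$svm$cv_accuracy))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  manifest$hash <- unname(tools::md5sum(tmp))
  manifest
}

#' @export
print.carbmdd <- function(x, ...) {
  cat(sprintf("Two-layer carbonylation-site model (%s residues)\n", x$residue))
  cat(sprintf("  training fragments: %d positive / %d negative (21-mer: n = %d)\n",
              nrow(x$dataset$positives), nrow(x$dataset$negatives),
              x$control$n))
  cat(sprintf("  motif subgroups: %d\n", length(x$profiles)))
  for (p in x$profiles)
    cat(sprintf("    %s: %d members, bit threshold %.2f\n",
                p$subgroup_id, p$size, p$bit_threshold))
  cat(sprintf("  second layer: RBF-SVM, cost = %g, gamma = %g (grid CV acc %.3f)\n",
              x$svm$cost, x$svm$gamma, x$svm$cv_accuracy))
  invisible(x)
}

#' @export
summary.carbmdd <- function(object, ...) {
  tr <- object$tree
  splits <- list()
  rec <- function(node) {
    if (!node$is_leaf) {
      splits[[length(splits) + 1L]] <<- data.frame(
        position = node$split_position, group = node$split_group_name,
        chi2 = node$chi2, size = length(node$members))
      rec(node$children$in_group); rec(node$children$out_group)
    }
  }
  rec(tr$root)
  out <- list(residue = object$residue,
              splits = if (length(splits)) do.call(rbind, splits)
              else data.frame(),
              subgroups = coef(object),
              svm = object$manifest$svm,
              manifest_hash = object$manifest$hash)
  class(out) <- "summary.carbmdd"
  out
}

#' @export
print.summary.carbmdd <- function(x, ...) {
  cat(sprintf("MDD motif decomposition for %s sites\n", x$residue))
  if (nrow(x$splits)) {
    cat("Splits (depth-first):\n")
    print(x$splits, row.names = FALSE)
  } else cat("No significant positional dependence; single subgroup.\n")
  cat("Subgroups:\n")
  print(x$subgroups, row.names = FALSE)
  cat(sprintf("Second-layer SVM: cost %g, gamma %g, grid CV accuracy %.3f\n",
              x$svm$cost, x$svm$gamma, x$svm$cv_accuracy))
  invisible(x)
}

#' @export
coef.carbmdd <- function(object, ...) {
  data.frame(subgroup = vapply(object$profiles, `[[`, character(1),
                               "subgroup_id"),
             size = vapply(object$profiles, `[[`, numeric(1), "size"),
             bit_threshold = vapply(object$profiles, `[[`, numeric(1),
                                    "bit_threshold"))
}

#' Predict carbonylation sites
#'
#' With \code{proteins}, every K/R/T/P residue of the fitted type is
#' windowed and scored; with \code{windows}, precomputed fragments are
#' scored directly. Each site receives the second-layer decision value, a
#' positive/negative call, and the motif subgroup whose profile scores it
#' highest.
#'
#' @param object A fitted \code{carbmdd}.
#' @param proteins Named character vector of protein sequences.
#' @param windows Character vector of site windows (alternative input).
#' @param ... Unused.
#' @return Data frame with columns \code{protein_id}, \code{position},
#'   \code{residue}, \code{window}, \code{score}, \code{label},
#'   \code{matched_subgroup} (site columns NA for window input).
#' @export
predict.carbmdd <- function(object, proteins = NULL, windows = NULL, ...) {
  if (is.null(windows)) {
    if (is.null(proteins))
      stop("supply either proteins or windows", call. = FALSE)
    tab <- new_fragment_table()
    for (pid in names(proteins)) {
      check_protein(proteins[[pid]], pid)
      hits <- gregexpr(object$residue, proteins[[pid]], fixed = TRUE)[[1]]
      hits <- hits[hits > 0L]
      if (!length(hits)) next
      win <- vapply(hits, function(p)
        extract_fragment(proteins[[pid]], p, object$control$n, pid),
        character(1))
      tab <- rbind(tab, new_fragment_table(win, NA_character_, pid,
                                           as.integer(hits)))
    }
    if (!nrow(tab))
      return(data.frame(protein_id = character(), position = integer(),
                        residue = character(), window = character(),
                        score = numeric(), label = character(),
                        matched_subgroup = character(),
                        stringsAsFactors = FALSE))
    windows <- tab$window
    meta <- tab[c("protein_id", "position")]
  } else {
    meta <- data.frame(protein_id = NA_character_,
                       position = NA_integer_)[rep(1L, length(windows)), ]
  }
  scores <- bitscore_vector(object$profiles, windows)
  out <- predict(object$svm, scores)
  matched <- colnames(scores)[max.col(scores, ties.method = "first")]
  res <- data.frame(protein_id = meta$protein_id, position = meta$position,
                    residue = object$residue, window = windows,
                    score = out$score, label = out$label,
                    matched_subgroup = matched, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Plot the training ROC curve of a fitted model
#'
#' Resubstitution ROC of the second-layer decision values on the training
#' fragments (an optimistic view; use \code{\link{cross_validate}} for an
#' honest estimate).
#'
#' @param x A fitted \code{carbmdd}.
#' @param ... Passed to \code{plot}.
#' @export
plot.carbmdd <- function(x, ...) {
  windows <- c(x$dataset$positives$window, x$dataset$negatives$window)
  truth <- rep(c("positive", "negative"),
               c(nrow(x$dataset$positives), nrow(x$dataset$negatives)))
  scores <- predict(x, windows = windows)$score
  roc <- roc_auc(scores, truth)
  plot(roc$points$fpr, roc$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Training ROC, %s sites (AUC = %.3f)",
                      x$residue, roc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(roc)
}
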