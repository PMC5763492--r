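test_that("metrics reproduce the canonical confusion tables", {
  perfect <- compute_metrics(50, 100, 0, 0)
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$Sn, 1)
  expect_equal(perfect$Sp, 1)
  expect_equal(perfect$Acc, 1)

  expect_equal(compute_metrics(25, 25, 25, 25)$MCC, 0)
  expect_equal(compute_metrics(0, 0, 10, 10)$MCC, -1)
  # degenerate denominator convention
  expect_equal(compute_metrics(0, 5, 0, 5)$MCC, 0)
  expect_error(compute_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(55)
  for (i in 1:50) {
    cc <- as.list(sample(0:40, 4L, TRUE))
    names(cc) <- c("tp", "tn", "fp", "fn")
    if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) next
    m <- compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
    P <- cc$tp + cc$fn; N <- cc$tn + cc$fp
    expect_equal(m$Acc, (m$Sn * P + m$Sp * N) / (P + N), tolerance = 1e-12)
    # MCC symmetric under simultaneous class swap
    sw <- compute_metrics(cc$tn, cc$tp, cc$fn, cc$fp)
    expect_equal(m$MCC, sw$MCC, tolerance = 1e-12)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("AUC follows the rank method with half credit for ties", {
  sep <- roc_auc(c(5, 6, 7, 1, 2), rep(c("positive", "negative"), c(3, 2)))
  expect_equal(sep$auc, 1)
  expect_equal(sep$points$fpr[length(sep$points$fpr)], 1)
  expect_equal(sep$points$tpr[length(sep$points$tpr)], 1)

  tied <- roc_auc(rep(3, 10), rep(c("positive", "negative"), 5))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")
})

test_that("AUC equals the pairwise-comparison oracle on random scores", {
  set.seed(500)
  scores <- round(rnorm(500L), 1)          # rounding forces ties
  labels <- sample(rep(c("positive", "negative"), c(200L, 300L)))
  auc <- roc_auc(scores, labels)$auc
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  expect_equal(auc, wins / (length(pos) * length(neg)), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(scores), labels)$auc, auc, tolerance = 1e-12)
})

test_that("stratified folds are near-equal and exhaustive", {
  labels <- rep(c("positive", "negative"), c(103L, 206L))
  fold <- carbmotif:::stratified_folds(labels, 5L, seed = 2L)
  expect_equal(length(fold), 309L)
  for (cl in c("positive", "negative")) {
    sizes <- table(fold[labels == cl])
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_equal(sort(unique(fold)), 1:5)
  expect_error(carbmotif:::stratified_folds(rep("positive", 3L), 5L, 1L),
               "folds")
})

test_that("pooled cross-validation detects overfitting of a memorizer", {
  pos <- random_windows(40L, seed = 1L)
  neg <- random_windows(80L, seed = 2L)
  # memorizer: recalls training labels exactly, guesses 'negative' otherwise
  memorizer <- function(p, n) list(pos = p, neg = n)
  score_mem <- function(model, w) {
    lab <- ifelse(w %in% model$pos, "positive", "negative")
    data.frame(score = as.numeric(w %in% model$pos), label = lab)
  }
  cv <- cross_validate(pos, neg, memorizer, score_mem, k = 5L, seed = 4L)
  infold <- score_mem(memorizer(pos, neg), c(pos, neg))
  in_acc <- mean(infold$label == rep(c("positive", "negative"), c(40L, 80L)))
  expect_equal(in_acc, 1)
  expect_lte(cv$metrics$Acc, in_acc)
  expect_equal(cv$metrics$Sn, 0)        # unseen positives all missed

  # each sample is scored exactly once, in its own validation fold
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  cc <- cv$counts
  expect_equal(cc$tp + cc$fn, 40L)
  expect_equal(cc$tn + cc$fp, 80L)
  # pooled metrics equal metrics recomputed from concatenated counts
  expect_equal(cv$metrics, compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn))
})

test_that("repeated negative resampling averages per-repeat performance", {
  sf <- synth_fragments(30L, 300L,
                        motifs = list(motif_spec(-3L, c("K", "R"), 1, 8L)),
                        seed = 3L)
  fit_fun <- function(p, n) {
    m <- train_profile(p, 0.5)
    calibrate_threshold(m, p, n)
  }
  score_fun <- function(model, w) {
    s <- bit_score(model, w)
    data.frame(score = s,
               label = ifelse(s > model$bit_threshold, "positive",
                              "negative"))
  }
  out <- repeated_resampling_eval(sf$positives, sf$negatives, fit_fun,
                                  score_fun, repeats = 5L, ratio = 2L,
                                  k = 5L, seed = 100L)
  expect_equal(nrow(out$per_repeat), 5L)
  expect_gte(out$mean$Sn, min(out$per_repeat$Sn))
  expect_lte(out$mean$Sn, max(out$per_repeat$Sn))

  # repeats = 1 reduces to a single cross-validation at the derived seed
  one <- repeated_resampling_eval(sf$positives, sf$negatives, fit_fun,
                                  score_fun, repeats = 1L, ratio = 2L,
                                  k = 5L, seed = 200L)
  idx <- withr::with_seed(201L, sample.int(300L, 60L))
  direct <- cross_validate(sf$positives, sf$negatives[idx], fit_fun,
                           score_fun, k = 5L, seed = 201L)
  expect_equal(one$per_repeat$Acc, direct$metrics$Acc)
  expect_equal(one$per_repeat$AUC, direct$auc)

  expect_error(repeated_resampling_eval(sf$positives, sf$negatives[1:10],
                                        fit_fun, score_fun),
               "pool too small")
})

test_that("independent testing refuses overlapping train/test sites", {
  sf <- synth_fragments(40L, 80L,
                        motifs = list(motif_spec(-3L, c("K", "R"), 1, 8L)),
                        seed = 6L)
  fit <- train_profile(sf$positives)
  fit <- calibrate_threshold(fit, sf$positives, sf$negatives)
  score_fun <- function(model, w) {
    s <- bit_score(model, w)
    data.frame(score = s,
               label = ifelse(s > model$bit_threshold, "positive",
                              "negative"))
  }
  held <- synth_fragments(30L, 60L,
                          motifs = list(motif_spec(-3L, c("K", "R"), 1, 8L)),
                          seed = 7L)
  res <- independent_test(fit, held$positives, held$negatives,
                          train_keys = paste("train", seq_len(120L)),
                          test_keys = paste("test", seq_len(90L)),
                          score_fun = score_fun)
  expect_gt(res$metrics$Acc, 0.7)       # drawn from the training distribution
  expect_gt(res$auc, 0.8)

  expect_error(independent_test(fit, held$positives, held$negatives,
                                train_keys = c("p1 10", "p2 20"),
                                test_keys = c("p2 20", "p9 9"),
                                score_fun = score_fun),
               "overlap")
})
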