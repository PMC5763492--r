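# Shared fixture builders (everything is generated in code at test time).

# Wrap plain window vectors into a carb_dataset so the fitter can be driven
# without proteins.
windows_to_dataset <- function(positives, negatives, residue = "K", n = 10L) {
  structure(list(
    residue = residue,
    positives = data.frame(window = positives, label = "positive",
                           protein_id = sprintf("pos%04d", seq_along(positives)),
                           position = n + 1L, stringsAsFactors = FALSE),
    negatives = data.frame(window = negatives, label = "negative",
                           protein_id = sprintf("neg%04d", seq_along(negatives)),
                           position = n + 1L, stringsAsFactors = FALSE),
    n = as.integer(n)), class = "carb_dataset")
}

# Random windows with a fixed centre residue, uniform background.
random_windows <- function(k, n = 10L, residue = "K", seed = 1L) {
  synth_fragments(k, 0L, residue, motifs = list(), n = n,
                  seed = seed)$positives
}

# Small SVM grid to keep unit tests quick; acceptance uses the default grid.
small_grid <- function() list(cost = 2^seq(-1L, 5L, 2L),
                              gamma = 2^seq(-7L, -1L, 2L))

small_control <- function(...) {
  carb_control(svm_grid = small_grid(), ...)
}
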