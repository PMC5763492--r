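# Run expr with a locally seeded RNG, restoring any prior RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Planted positional motif specification
#'
#' Describes a motif planted into synthetic positive fragments: a residue
#' set at one signed window offset, present with probability
#' \code{penetrance}, optionally co-occurring with a second residue set at
#' another offset (the co-occurrence is what creates chi-squared dependence
#' between the two positions).
#'
#' @param position Signed window offset (non-zero) carrying the motif.
#' @param residues Character vector of residues the motif draws from.
#' @param penetrance Probability a positive fragment carries the motif.
#' @param co_position Optional second offset; when given, motif carriers
#'   also receive a residue from \code{co_residues} there.
#' @param co_residues Residues for the co-position (default same set).
#' @return A \code{motif_spec} list.
#' @export
motif_spec <- function(position, residues, penetrance = 0.9,
                       co_position = NULL, co_residues = residues) {
  if (position == 0)
    stop("motif position must not be the centre", call. = FALSE)
  if (penetrance <= 0 || penetrance > 1)
    stop("penetrance must be in (0, 1]", call. = FALSE)
  if (!all(residues %in% AA20) || !all(co_residues %in% AA20))
    stop("motif residues must be standard amino acids", call. = FALSE)
  structure(list(position = as.integer(position), residues = residues,
                 penetrance = penetrance,
                 co_position = if (is.null(co_position)) NULL
                 else as.integer(co_position),
                 co_residues = co_residues),
            class = "motif_spec")
}

#' Background residue distributions for the generator
#'
#' \code{"uniform"} draws every residue at 1/20. \code{"krtp"} mimics the
#' compositional bias seen around oxidised sites in curated data: K, R, T,
#' P and L are enriched relative to the remaining residues.
#'
#' @param background \code{"uniform"}, \code{"krtp"}, or a 20-vector of
#'   probabilities.
#' @return Named probability vector over the 20 amino acids.
#' @export
background_probs <- function(background = "uniform") {
  if (is.numeric(background)) return(normalize_background(background))
  background <- match.arg(background, c("uniform", "krtp"))
  if (background == "uniform")
    return(stats::setNames(rep(1 / 20, 20L), AA20))
  w <- stats::setNames(rep(1, 20L), AA20)
  w[c("K", "R", "T", "P", "L")] <- c(3, 2.5, 2, 2, 2.5)
  w / sum(w)
}

# One window string: background everywhere, centre residue fixed, motif
# planting applied for carriers. Uses the RNG in effect.
make_window <- function(n, residue, probs, motif = NULL) {
  w <- sample(AA20, 2L * n + 1L, replace = TRUE, prob = probs)
  w[n + 1L] <- residue
  if (!is.null(motif) && stats::runif(1) <= motif$penetrance) {
    w[n + 1L + motif$position] <- sample(motif$residues, 1L)
    if (!is.null(motif$co_position))
      w[n + 1L + motif$co_position] <- sample(motif$co_residues, 1L)
  }
  paste(w, collapse = "")
}

#' Generate synthetic site fragments with planted motifs
#'
#' Positive fragments are assigned round-robin to the motif subfamilies in
#' \code{motifs} and carry their subfamily's motif with its penetrance;
#' negative fragments are pure background. Fully reproducible under
#' \code{seed}.
#'
#' @param n_positive,n_negative Fragment counts.
#' @param residue Centre residue (K, R, T or P).
#' @param motifs List of \code{\link{motif_spec}}s (one per subfamily);
#'   empty list gives motif-free positives.
#' @param background See \code{\link{background_probs}}.
#' @param n Window half-width (default 10).
#' @param seed Integer seed.
#' @return List with \code{positives}, \code{negatives} (window vectors),
#'   \code{truth} (subfamily index per positive), \code{residue}, \code{n}.
#' @export
synth_fragments <- function(n_positive, n_negative, residue = "K",
                            motifs = list(motif_spec(-3L, c("K", "R"),
                                                     penetrance = 0.9,
                                                     co_position = 8L)),
                            background = "uniform", n = 10L, seed = 1L) {
  residue <- match.arg(residue, SITE_RESIDUES)
  probs <- background_probs(background)
  with_seed(seed, {
    truth <- if (length(motifs))
      rep_len(seq_along(motifs), n_positive) else integer(n_positive)
    positives <- vapply(seq_len(n_positive), function(i) {
      motif <- if (length(motifs)) motifs[[truth[[i]]]]
      make_window(n, residue, probs, motif)
    }, character(1))
    negatives <- vapply(seq_len(n_negative), function(i)
      make_window(n, residue, probs), character(1))
    list(positives = positives, negatives = negatives, truth = truth,
         residue = residue, n = as.integer(n))
  })
}

#' Generate annotated synthetic proteins
#'
#' Builds background proteins and plants positive site windows at spaced
#' interior positions, returning the proteins, a positive-site annotation
#' table, and the ground-truth subfamily of every planted site — the same
#' three artefacts a curated training set provides.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Length of each protein.
#' @param n_positive_sites Number of planted positive sites.
#' @param residue Site residue type.
#' @param motifs,background,n,seed As in \code{\link{synth_fragments}}.
#' @return List with \code{proteins} (named character vector),
#'   \code{sites} (data frame: protein_id, position, residue, label) and
#'   \code{truth} (data frame adding the subfamily index).
#' @export
synth_proteins <- function(n_proteins = 40L, protein_length = 240L,
                           n_positive_sites = 100L, residue = "K",
                           motifs = list(motif_spec(-3L, c("K", "R"),
                                                    penetrance = 0.9,
                                                    co_position = 8L)),
                           background = "uniform", n = 10L, seed = 1L) {
  residue <- match.arg(residue, SITE_RESIDUES)
  probs <- background_probs(background)
  w <- 2L * n + 1L
  slots_per_protein <- max(0L, (protein_length - n - (n + 1L)) %/% (w + 1L) + 1L)
  if (n_proteins * slots_per_protein < n_positive_sites)
    stop("proteins too short/few for the requested number of sites",
         call. = FALSE)
  with_seed(seed, {
    ids <- sprintf("synthP%03d", seq_len(n_proteins))
    proteins <- stats::setNames(vapply(ids, function(id)
      paste(sample(AA20, protein_length, replace = TRUE, prob = probs),
            collapse = ""), character(1)), ids)
    # spaced interior slots so planted windows never overlap
    slot_pos <- n + 1L + (seq_len(slots_per_protein) - 1L) * (w + 1L)
    all_slots <- expand.grid(protein = seq_len(n_proteins),
                             position = slot_pos)
    pick <- all_slots[sample.int(nrow(all_slots), n_positive_sites), ]
    truth_sub <- if (length(motifs))
      rep_len(seq_along(motifs), n_positive_sites) else
      integer(n_positive_sites)
    for (i in seq_len(n_positive_sites)) {
      motif <- if (length(motifs)) motifs[[truth_sub[[i]]]]
      win <- make_window(n, residue, probs, motif)
      p <- pick$position[[i]]
      pid <- ids[[pick$protein[[i]]]]
      seqchars <- proteins[[pid]]
      substr(seqchars, p - n, p + n) <- win
      proteins[[pid]] <- seqchars
    }
    sites <- data.frame(protein_id = ids[pick$protein],
                        position = as.integer(pick$position),
                        residue = residue, label = "positive",
                        stringsAsFactors = FALSE)
    ord <- order(sites$protein_id, sites$position)
    list(proteins = proteins,
         sites = sites[ord, , drop = FALSE],
         truth = cbind(sites, subfamily = truth_sub)[ord, , drop = FALSE])
  })
}

#' Benchmark-scale synthetic dataset for one residue type
#'
#' Fragment dataset at the scale of curated mammalian carbonylation
#' training data: 256 positives / 512 negatives for K, 115/230 for R,
#' 109/218 for T and 109/218 for P, drawn on the KRTP-enriched background
#' with a residue-specific planted basic-group motif (K at offset -3, R at
#' +10, T at +2, P at +6).
#'
#' @param residue One of K, R, T, P.
#' @param seed Integer seed.
#' @return As \code{\link{synth_fragments}}.
#' @export
synth_benchmark_dataset <- function(residue = "K", seed = 1L) {
  residue <- match.arg(residue, SITE_RESIDUES)
  counts <- list(K = c(256L, 512L), R = c(115L, 230L),
                 T = c(109L, 218L), P = c(109L, 218L))[[residue]]
  motifs <- switch(residue,
    K = list(motif_spec(-3L, c("K", "R"), 0.7, co_position = 8L)),
    R = list(motif_spec(10L, c("R", "K", "H"), 0.7, co_position = -10L)),
    T = list(motif_spec(2L, c("K", "R"), 0.7, co_position = -9L)),
    P = list(motif_spec(6L, c("R", "K"), 0.7, co_position = -10L)))
  synth_fragments(counts[[1]], counts[[2]], residue, motifs,
                  background = "krtp", seed = seed)
}

#' Write synthetic proteins and annotations to disk
#'
#' FASTA for the proteins, TSV for the site table and JSON for the truth —
#' the plain-text interchange trio the rest of the package reads back.
#'
#' @param synth Output of \code{\link{synth_proteins}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "proteins.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(synth$proteins), fa)
  tsv <- file.path(dir, "sites.tsv")
  utils::write.table(synth$sites, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "truth.json")
  jsonlite::write_json(synth$truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, sites = tsv, truth = js))
}
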