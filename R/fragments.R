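#' Read proteins from a FASTA file
#'
#' Wraps \code{Biostrings::readAAStringSet} and validates that every sequence
#' uses only the 20 standard one-letter amino-acid codes.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of protein sequences; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aas)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  for (i in seq_along(seqs)) check_protein(seqs[[i]], names(seqs)[[i]])
  seqs
}

check_protein <- function(sequence, id = "protein") {
  if (!nzchar(sequence))
    stop(sprintf("protein '%s' has an empty sequence", id), call. = FALSE)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), AA20)
  if (length(bad))
    stop(sprintf("protein '%s' contains non-standard symbols: %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read site annotations from a TSV file
#'
#' Expected columns: \code{protein_id}, \code{position} (1-based),
#' \code{residue} (one of K, R, T, P) and \code{label}
#' (\code{positive}/\code{negative}). Lines starting with \code{#} are
#' ignored.
#'
#' @param path Path to the tab-separated annotation file.
#' @return A data frame with the four columns above.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("site table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$position <- as.integer(df$position)
  df[need]
}

#' Extract a fixed-width site window from a protein
#'
#' Returns the 2n+1 residues centred on \code{position}; positions that fall
#' outside the protein are padded with the dummy symbol \code{'-'}, so the
#' window length is always 2n+1.
#'
#' @param sequence Protein sequence (single string over the 20 amino acids).
#' @param position 1-based position of the site in the protein.
#' @param n Window half-width; the default 10 gives 21-mer windows.
#' @param id Protein identifier used in error messages.
#' @return Single string of length \code{2 * n + 1}.
#' @examples
#' extract_fragment("MKSLVK", 2, n = 3)
#' @export
extract_fragment <- function(sequence, position, n = 10L, id = "protein") {
  len <- nchar(sequence)
  if (position < 1L || position > len)
    stop(sprintf("site position %d is outside protein '%s' (length %d)",
                 position, id, len), call. = FALSE)
  from <- position - n
  to <- position + n
  core <- substr(sequence, max(1L, from), min(len, to))
  pad_l <- max(0L, 1L - from)
  pad_r <- max(0L, to - len)
  paste0(strrep(DUMMY, pad_l), core, strrep(DUMMY, pad_r))
}

new_fragment_table <- function(window = character(), label = character(),
                               protein_id = character(),
                               position = integer()) {
  data.frame(window = window, label = label, protein_id = protein_id,
             position = position, stringsAsFactors = FALSE)
}

#' Build the candidate-site dataset for one residue type
#'
#' Extracts a window for every annotated positive site of \code{residue} and
#' enumerates every non-annotated occurrence of that residue in the proteins
#' as the negative pool, as is conventional when curated positives are the
#' only labelled data.
#'
#' @param proteins Named character vector of protein sequences.
#' @param sites Data frame of positive annotations with columns
#'   \code{protein_id}, \code{position}, \code{residue} (rows for other
#'   residues are ignored). A \code{label} column, if present, restricts to
#'   rows labelled \code{positive}.
#' @param residue Site residue type: one of \code{"K"}, \code{"R"},
#'   \code{"T"}, \code{"P"}.
#' @param n Window half-width (default 10).
#' @return A \code{carb_dataset}: list with elements \code{residue},
#'   \code{positives}, \code{negatives} (fragment data frames) and \code{n}.
#' @export
build_candidate_sites <- function(proteins, sites, residue, n = 10L) {
  residue <- match.arg(residue, SITE_RESIDUES)
  if (!is.null(sites$label)) sites <- sites[sites$label == "positive", ]
  if (!is.null(sites$residue)) sites <- sites[sites$residue == residue, ]

  pos_key <- character(0)
  pos <- new_fragment_table()
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      pid <- sites$protein_id[[i]]
      p <- sites$position[[i]]
      if (!pid %in% names(proteins))
        stop(sprintf("annotation references unknown protein '%s'", pid),
             call. = FALSE)
      seq <- proteins[[pid]]
      if (p < 1L || p > nchar(seq) || substr(seq, p, p) != residue)
        stop(sprintf(
          "annotation mismatch for protein '%s' position %d: expected %s",
          pid, p, residue), call. = FALSE)
    }
    win <- mapply(function(pid, p) extract_fragment(proteins[[pid]], p, n, pid),
                  sites$protein_id, sites$position, USE.NAMES = FALSE)
    pos <- new_fragment_table(win, "positive", sites$protein_id,
                              as.integer(sites$position))
    pos_key <- paste(pos$protein_id, pos$position)
    dup <- duplicated(pos_key)
    pos <- pos[!dup, , drop = FALSE]
    pos_key <- pos_key[!dup]
  }

  neg <- new_fragment_table()
  for (pid in names(proteins)) {
    hits <- gregexpr(residue, proteins[[pid]], fixed = TRUE)[[1]]
    hits <- hits[hits > 0L]
    if (!length(hits)) next
    keep <- !(paste(pid, hits) %in% pos_key)
    hits <- hits[keep]
    if (!length(hits)) next
    win <- vapply(hits, function(p) extract_fragment(proteins[[pid]], p, n, pid),
                  character(1))
    neg <- rbind(neg, new_fragment_table(win, "negative", pid,
                                         as.integer(hits)))
  }
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(residue = residue, positives = pos, negatives = neg,
                 n = as.integer(n)),
            class = "carb_dataset")
}

#' @export
print.carb_dataset <- function(x, ...) {
  cat(sprintf("Candidate-site dataset (%s residues, window %d-mer)\n",
              x$residue, 2L * x$n + 1L))
  cat(sprintf("  positives: %d\n  negatives: %d\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

# Ungapped fractional identity between two equal-length windows: matches
# divided by the number of positions where both are non-dummy.
pair_identity <- function(a, b) {
  ok <- a != DUMMY & b != DUMMY
  if (!any(ok)) return(0)
  sum(a[ok] == b[ok]) / sum(ok)
}

#' Greedy redundancy reduction of site windows
#'
#' Scans fragments in input order and drops any fragment whose ungapped
#' positional identity with an already retained fragment (or with any
#' fragment in \code{reference}) reaches \code{identity_threshold}. Identity
#' is matches over compared positions where neither window has the dummy
#' symbol. This removes near-duplicate windows and, via \code{reference},
#' negatives too similar to positives.
#'
#' @param windows Character vector of equal-length windows.
#' @param identity_threshold Fraction in (0, 1]; default 0.5.
#' @param reference Optional character vector of windows to also compare
#'   against (e.g. the positive set when filtering negatives).
#' @return Logical vector marking the retained windows (same order as input).
#' @export
redundancy_keep <- function(windows, identity_threshold = 0.5,
                            reference = NULL) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  if (!length(windows)) return(logical(0))
  m <- window_matrix(windows)
  ref <- if (length(reference)) {
    r <- window_matrix(reference)
    if (ncol(r) != ncol(m))
      stop("fragments have mixed window lengths", call. = FALSE)
    r
  }
  keep <- logical(nrow(m))
  kept_rows <- integer(0)
  for (i in seq_len(nrow(m))) {
    w <- m[i, ]
    similar <- FALSE
    if (!is.null(ref)) {
      for (j in seq_len(nrow(ref))) {
        if (pair_identity(w, ref[j, ]) >= identity_threshold) {
          similar <- TRUE; break
        }
      }
    }
    if (!similar) {
      for (j in kept_rows) {
        if (pair_identity(w, m[j, ]) >= identity_threshold) {
          similar <- TRUE; break
        }
      }
    }
    keep[i] <- !similar
    if (!similar) kept_rows <- c(kept_rows, i)
  }
  keep
}

#' @rdname redundancy_keep
#' @param fragments Fragment data frame (with a \code{window} column) to
#'   filter; returned with dropped rows removed, original order preserved.
#' @export
reduce_redundancy <- function(fragments, identity_threshold = 0.5,
                              reference = NULL) {
  keep <- redundancy_keep(fragments$window, identity_threshold, reference)
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample negatives at a fixed ratio to the positives
#'
#' Draws \code{ratio} times as many negatives as there are positives,
#' uniformly without replacement from the negative pool. Reproducible under
#' \code{seed}.
#'
#' @param dataset A \code{carb_dataset}.
#' @param ratio Negative:positive ratio (default 2).
#' @param seed Integer seed for the draw.
#' @return The dataset with \code{negatives} replaced by the sample.
#' @export
sample_negatives <- function(dataset, ratio = 2L, seed = 1L) {
  need <- ratio * nrow(dataset$positives)
  pool <- nrow(dataset$negatives)
  if (pool < need)
    stop(sprintf("negative pool too small: need %d, have %d (short by %d)",
                 need, pool, need - pool), call. = FALSE)
  idx <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(pool, need)
  })
  dataset$negatives <- dataset$negatives[sort(idx), , drop = FALSE]
  rownames(dataset$negatives) <- NULL
  dataset
}

#' Write / read fragment tables as TSV
#'
#' Plain tab-separated export with columns \code{window}, \code{label},
#' \code{protein_id}, \code{position}.
#'
#' @param fragments Fragment data frame.
#' @param path Output (or input) file path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$position <- as.integer(df$position)
  df
}
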