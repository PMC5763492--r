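# PSI-BLAST column order in ASCII PSSM output.
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the standard ASCII PSSM dialect (header line of residue column
#' labels, then one row per query position: index, residue, 20 integer
#' log-odds scores; trailing percentage/information columns are ignored).
#'
#' @param path Path to the ASCII PSSM file.
#' @return A \code{pssm_profile}: list with \code{scores} (rows x 20 matrix,
#'   columns reordered to the canonical alphabetical amino-acid order) and
#'   \code{row_residues} (the query residue of each row).
#' @export
load_pssm <- function(path) {
  lines <- readLines(path)
  header_i <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) >= 20L && all(tok[1:20] %in% AA20)) {
      header_i <- i
      col_order <- tok[1:20]
      break
    }
  }
  if (is.na(header_i))
    stop("malformed PSSM file: no residue header line found in '", path, "'",
         call. = FALSE)
  scores <- list()
  residues <- character(0)
  for (i in seq.int(header_i + 1L, length(lines))) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) break
    tok <- strsplit(line, "\\s+")[[1]]
    if (is.na(suppressWarnings(as.integer(tok[[1]])))) break
    if (length(tok) < 22L || !tok[[2]] %in% AA20)
      stop(sprintf("malformed PSSM row at line %d of '%s'", i, path),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals))
      stop(sprintf("malformed PSSM row at line %d of '%s'", i, path),
           call. = FALSE)
    residues <- c(residues, tok[[2]])
    scores[[length(scores) + 1L]] <- vals
  }
  if (!length(scores))
    stop("malformed PSSM file: no score rows in '", path, "'", call. = FALSE)
  m <- do.call(rbind, scores)
  colnames(m) <- col_order
  m <- m[, AA20, drop = FALSE]
  structure(list(scores = m, row_residues = residues),
            class = "pssm_profile")
}

#' Internal position-specific log-odds matrix
#'
#' Fallback profile generator used when precomputed PSI-BLAST output is not
#' available: per-position log2 odds of each residue in the training windows
#' against a background distribution, with an additive pseudocount.
#'
#' @param windows Positive training windows (equal length).
#' @param pseudocount Additive pseudocount (default 1).
#' @param background Background probabilities over the 20 amino acids
#'   (default uniform).
#' @return Numeric (2n+1) x 20 log-odds matrix in canonical column order.
#' @export
compute_pssm_matrix <- function(windows, pseudocount = 1,
                                background = rep(1 / 20, 20L)) {
  if (!length(windows)) stop("empty training set", call. = FALSE)
  background <- normalize_background(background)
  m <- window_matrix(windows)
  out <- matrix(0, ncol(m), 20L, dimnames = list(NULL, AA20))
  for (p in seq_len(ncol(m))) {
    r <- m[, p]
    r <- r[r != DUMMY]
    cnt <- as.numeric(table(factor(r, levels = AA20)))
    prob <- (cnt + pseudocount) / (length(r) + 20 * pseudocount)
    out[p, ] <- log2(prob / background)
  }
  out
}

#' @rdname compute_pssm_matrix
#' @param window A single site window whose residues become the profile's
#'   row residues.
#' @param scores Log-odds matrix from \code{compute_pssm_matrix} (or parsed
#'   PSI-BLAST scores) with one row per window position.
#' @export
make_pssm_profile <- function(window, scores) {
  res <- strsplit(window, "", fixed = TRUE)[[1]]
  if (length(res) != nrow(scores))
    stop("window length does not match the score matrix", call. = FALSE)
  structure(list(scores = scores, row_residues = res),
            class = "pssm_profile")
}

#' Aggregate a PSSM profile into a 400-dimensional feature vector
#'
#' Rows of the profile sharing the same residue are summed into a 20 x 20
#' matrix (residues absent from the window give zero rows), every element is
#' divided by the window length and squashed through the logistic
#' 1 / (1 + exp(-x)), and the matrix is flattened row-major in canonical
#' residue order.
#'
#' @param profile A \code{pssm_profile}.
#' @return Numeric vector of length 400 with values in (0, 1).
#' @export
encode_pssm <- function(profile) {
  m <- profile$scores
  res <- profile$row_residues
  w <- nrow(m)
  agg <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  for (a in AA20) {
    rows <- which(res == a)
    if (length(rows))
      agg[a, ] <- colSums(m[rows, , drop = FALSE])
  }
  v <- as.vector(t(1 / (1 + exp(-agg / w))))
  names(v) <- as.vector(t(outer(AA20, AA20, paste0)))
  v
}

normalize_background <- function(background) {
  if (length(background) != 20L)
    stop("background must have 20 probabilities", call. = FALSE)
  if (is.null(names(background))) names(background) <- AA20
  background <- background[AA20]
  if (anyNA(background) || any(background <= 0))
    stop("background probabilities must be positive for all 20 residues",
         call. = FALSE)
  background / sum(background)
}
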