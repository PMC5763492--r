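# Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
# All matrices and feature vectors in the package are ordered this way.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Dummy symbol used for terminus padding in site windows.
DUMMY <- "-"

SITE_RESIDUES <- c("K", "R", "T", "P")

#' Default biochemical grouping of the 20 amino acids
#'
#' Partition of the standard amino acids into five biochemical classes --
#' polar, acidic, basic, hydrophobic and aromatic -- used by the chi-squared
#' positional dependence test so that every contingency table has
#' (5-1)x(5-1) = 16 degrees of freedom. The dummy padding symbol maps to no
#' group and is excluded from all counts.
#'
#' @return Named integer vector mapping each one-letter amino-acid code to a
#'   group index 1..5, with a \code{groups} attribute giving the group names.
#' @examples
#' gm <- default_group_map()
#' gm[["K"]]  # basic
#' @export
default_group_map <- function() {
  groups <- c(polar = 1L, acidic = 2L, basic = 3L, hydrophobic = 4L,
              aromatic = 5L)
  map <- c(
    A = 4L, C = 1L, D = 2L, E = 2L, F = 5L, G = 1L, H = 3L, I = 4L,
    K = 3L, L = 4L, M = 4L, N = 1L, P = 4L, Q = 1L, R = 3L, S = 1L,
    T = 1L, V = 4L, W = 5L, Y = 1L
  )
  map <- map[AA20]
  attr(map, "groups") <- names(groups)
  map
}

# Validate a user-supplied group map: every amino acid in exactly one of 5
# groups, indices 1..5.
check_group_map <- function(group_map) {
  if (!all(AA20 %in% names(group_map)))
    stop("group map must cover all 20 amino acids", call. = FALSE)
  idx <- as.integer(group_map[AA20])
  if (anyNA(idx) || any(idx < 1L) || any(idx > 5L))
    stop("group indices must be integers in 1..5", call. = FALSE)
  invisible(idx)
}

# Split windows into a character matrix (one row per fragment, one column
# per window position). All windows must share a common length.
window_matrix <- function(windows) {
  lens <- nchar(windows)
  if (length(unique(lens)) > 1L)
    stop("fragments have mixed window lengths", call. = FALSE)
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), byrow = TRUE)
}

# Signed window offsets -n..+n for a window of length 2n+1.
window_offsets <- function(width) {
  n <- (width - 1L) %/% 2L
  seq.int(-n, n)
}
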