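#' Feature encodings of site windows
#'
#' Six numeric representations of fixed-width site windows, each returning
#' one row per fragment with columns in the canonical alphabetical
#' amino-acid order (A, C, D, ..., Y). Dummy padding positions never
#' contribute to counts.
#'
#' \describe{
#'   \item{AAC}{amino-acid composition: 20 relative frequencies over the
#'     non-dummy window residues; rows sum to 1.}
#'   \item{AAPC}{adjacent amino-acid pair composition: 400 relative
#'     frequencies of overlapping residue pairs; rows sum to 1.}
#'   \item{AA}{orthogonal binary (one-hot) coding: a 20-bit block per window
#'     position, all-zero for dummy positions; (2n+1) x 20 columns.}
#'   \item{PWM}{per-position lookup of the positive-set positional weight
#'     matrix; 2n+1 columns.}
#'   \item{PSSM}{PSI-BLAST profile aggregated to 20 x 20, scaled by the
#'     window length and squashed through the logistic; 400 columns.}
#'   \item{B62}{per position, the 20 BLOSUM62 substitution scores of the
#'     observed residue; (2n+1) x 20 columns.}
#' }
#'
#' @param windows Character vector of equal-length site windows.
#' @return Numeric matrix, one row per window.
#' @name encoders
NULL

#' @rdname encoders
#' @export
encode_aac <- function(windows) {
  m <- window_matrix(windows)
  out <- matrix(0, nrow(m), 20L, dimnames = list(NULL, AA20))
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    r <- r[r != DUMMY]
    if (!length(r))
      stop("cannot compute composition of an all-dummy fragment",
           call. = FALSE)
    tab <- table(factor(r, levels = AA20))
    out[i, ] <- as.numeric(tab) / length(r)
  }
  out
}

#' @rdname encoders
#' @export
encode_aapc <- function(windows) {
  pair_names <- as.vector(t(outer(AA20, AA20, paste0)))
  m <- window_matrix(windows)
  out <- matrix(0, nrow(m), 400L, dimnames = list(NULL, pair_names))
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    a <- r[-length(r)]
    b <- r[-1L]
    ok <- a != DUMMY & b != DUMMY
    if (!any(ok))
      stop("fragment has no adjacent non-dummy residue pair", call. = FALSE)
    pairs <- paste0(a[ok], b[ok])
    tab <- table(factor(pairs, levels = pair_names))
    out[i, ] <- as.numeric(tab) / sum(ok)
  }
  out
}

#' @rdname encoders
#' @export
encode_binary <- function(windows) {
  m <- window_matrix(windows)
  w <- ncol(m)
  out <- matrix(0, nrow(m), w * 20L)
  colnames(out) <- paste0("p", rep(window_offsets(w), each = 20L), ".",
                          rep(AA20, w))
  for (p in seq_len(w)) {
    hit <- match(m[, p], AA20)        # NA for dummy -> zero block
    ok <- !is.na(hit)
    out[cbind(which(ok), (p - 1L) * 20L + hit[ok])] <- 1
  }
  out
}

#' Positional weight matrix of the positive training set
#'
#' Relative frequency of each amino acid at each window position, computed
#' over the non-dummy residues observed at that position.
#'
#' @param windows Character vector of positive site windows (equal length).
#' @return Matrix with one row per window position (named by signed offset)
#'   and 20 columns; each row with any non-dummy observation sums to 1.
#' @export
build_pwm <- function(windows) {
  if (!length(windows)) stop("empty training set for PWM", call. = FALSE)
  m <- window_matrix(windows)
  offs <- window_offsets(ncol(m))
  pwm <- matrix(0, ncol(m), 20L,
                dimnames = list(sprintf("%+d", offs), AA20))
  for (p in seq_len(ncol(m))) {
    r <- m[, p]
    r <- r[r != DUMMY]
    if (length(r))
      pwm[p, ] <- as.numeric(table(factor(r, levels = AA20))) / length(r)
  }
  pwm
}

#' @rdname encoders
#' @param pwm Positional weight matrix from \code{\link{build_pwm}}.
#' @export
encode_pwm <- function(windows, pwm) {
  m <- window_matrix(windows)
  if (ncol(m) != nrow(pwm))
    stop("window length does not match the PWM", call. = FALSE)
  out <- matrix(0, nrow(m), ncol(m),
                dimnames = list(NULL, rownames(pwm)))
  for (p in seq_len(ncol(m))) {
    hit <- match(m[, p], AA20)
    ok <- !is.na(hit)
    out[ok, p] <- pwm[p, ][hit[ok]]
  }
  out
}

# BLOSUM62 restricted to the 20 standard residues, canonical order.
blosum62_matrix <- function() {
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()), envir = environment())
  b62[AA20, AA20]
}

#' @rdname encoders
#' @export
encode_blosum62 <- function(windows) {
  b62 <- blosum62_matrix()
  m <- window_matrix(windows)
  w <- ncol(m)
  out <- matrix(0, nrow(m), w * 20L)
  colnames(out) <- paste0("p", rep(window_offsets(w), each = 20L), ".",
                          rep(AA20, w))
  for (p in seq_len(w)) {
    hit <- match(m[, p], AA20)
    ok <- !is.na(hit)
    if (any(ok))
      out[ok, (p - 1L) * 20L + seq_len(20L)] <- b62[hit[ok], , drop = FALSE]
  }
  out
}

#' Encode fragments under a named scheme
#'
#' Dispatcher over the six encoders. The PWM scheme requires the positive
#' training windows (to build the positional weight matrix) or a prebuilt
#' matrix; the PSSM scheme requires one profile per fragment.
#'
#' @param windows Character vector of site windows.
#' @param scheme One of \code{"aac"}, \code{"aapc"}, \code{"aa"},
#'   \code{"pwm"}, \code{"pssm"}, \code{"b62"}.
#' @param pwm Positional weight matrix (scheme \code{"pwm"}).
#' @param profiles List of PSSM profiles, one per window (scheme
#'   \code{"pssm"}).
#' @return Numeric matrix, one row per fragment.
#' @export
encode_fragments <- function(windows,
                             scheme = c("aac", "aapc", "aa", "pwm",
                                        "pssm", "b62"),
                             pwm = NULL, profiles = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    aac = encode_aac(windows),
    aapc = encode_aapc(windows),
    aa = encode_binary(windows),
    pwm = {
      if (is.null(pwm)) stop("scheme 'pwm' needs a pwm matrix", call. = FALSE)
      encode_pwm(windows, pwm)
    },
    pssm = {
      if (is.null(profiles) || length(profiles) != length(windows))
        stop("scheme 'pssm' needs one profile per fragment", call. = FALSE)
      do.call(rbind, lapply(profiles, encode_pssm))
    },
    b62 = encode_blosum62(windows)
  )
}
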