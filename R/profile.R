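#' Train a position-specific profile model on a motif subgroup
#'
#' Per-position emission probabilities with an additive pseudocount:
#' emission(p, a) = (count of a at p + pseudocount) /
#' (non-dummy count at p + 20 * pseudocount). Fragments are fixed-length
#' and ungapped, so the profile has one emission row per window position;
#' fragments are scored in bits against a background distribution.
#'
#' @param windows Character vector of subgroup site windows (equal length).
#' @param pseudocount Additive pseudocount (default 0.5).
#' @param background Background probabilities over the 20 amino acids
#'   (default uniform 1/20).
#' @param subgroup_id Identifier stored with the model.
#' @return A \code{profile_model}: list with \code{emissions} (positions x
#'   20), \code{background}, \code{pseudocount}, \code{bit_threshold}
#'   (NA until calibrated) and \code{subgroup_id}.
#' @export
train_profile <- function(windows, pseudocount = 0.5,
                          background = rep(1 / 20, 20L),
                          subgroup_id = "profile") {
  if (!length(windows)) stop("empty subgroup", call. = FALSE)
  background <- normalize_background(background)
  m <- window_matrix(windows)
  offs <- window_offsets(ncol(m))
  em <- matrix(0, ncol(m), 20L,
               dimnames = list(sprintf("%+d", offs), AA20))
  for (p in seq_len(ncol(m))) {
    r <- m[, p]
    r <- r[r != DUMMY]
    cnt <- as.numeric(table(factor(r, levels = AA20)))
    denom <- length(r) + 20 * pseudocount
    em[p, ] <- if (denom > 0) (cnt + pseudocount) / denom else 1 / 20
  }
  structure(list(emissions = em, background = background,
                 pseudocount = pseudocount, bit_threshold = NA_real_,
                 subgroup_id = subgroup_id, size = length(windows)),
            class = "profile_model")
}

#' Bit score of site windows under a profile model
#'
#' Sum over non-dummy window positions of
#' log2(emission(p, residue) / background(residue)); dummy padding positions
#' contribute 0 bits.
#'
#' @param model A \code{profile_model}.
#' @param windows Character vector of site windows (same length as the
#'   model's window).
#' @return Numeric vector of bit scores.
#' @export
bit_score <- function(model, windows) {
  m <- window_matrix(windows)
  if (ncol(m) != nrow(model$emissions))
    stop("fragment length does not match the profile model", call. = FALSE)
  lo <- log2(sweep(model$emissions, 2L, model$background, "/"))
  out <- numeric(nrow(m))
  for (p in seq_len(ncol(m))) {
    hit <- match(m[, p], AA20)
    ok <- !is.na(hit)
    out[ok] <- out[ok] + lo[p, ][hit[ok]]
  }
  out
}

#' Calibrate a balanced bit-score threshold
#'
#' Sweeps candidate thresholds at the midpoints of consecutive distinct
#' observed scores and picks the one minimising |Sn - Sp| (a fragment is
#' called positive when its bit score exceeds the threshold). Ties are
#' broken by larger accuracy, then by the smaller threshold. Lowering the
#' threshold trades specificity for sensitivity, so the minimiser balances
#' the two error rates.
#'
#' @param model A \code{profile_model}.
#' @param positive_windows,negative_windows Calibration fragments.
#' @return The model with \code{bit_threshold} set.
#' @export
calibrate_threshold <- function(model, positive_windows, negative_windows) {
  if (!length(positive_windows) || !length(negative_windows))
    stop("both calibration sets must be non-empty", call. = FALSE)
  sp_scores <- bit_score(model, positive_windows)
  sn_scores <- bit_score(model, negative_windows)
  model$bit_threshold <- balanced_threshold(sp_scores, sn_scores)
  model
}

# Midpoint sweep shared by profile calibration; scores called positive when
# strictly above the threshold.
balanced_threshold <- function(pos_scores, neg_scores) {
  all_s <- sort(unique(c(pos_scores, neg_scores)))
  cand <- if (length(all_s) > 1L) {
    (all_s[-1L] + all_s[-length(all_s)]) / 2
  } else {
    all_s - 1
  }
  np <- length(pos_scores); nn <- length(neg_scores)
  best <- NULL
  for (t in cand) {
    sn <- sum(pos_scores > t) / np
    sp <- sum(neg_scores <= t) / nn
    acc <- (sn * np + sp * nn) / (np + nn)
    key <- c(abs(sn - sp), -acc, t)
    if (is.null(best) || key[1] < best[1] - 1e-12 ||
        (abs(key[1] - best[1]) <= 1e-12 &&
         (key[2] < best[2] - 1e-12 ||
          (abs(key[2] - best[2]) <= 1e-12 && t < best[3])))) {
      best <- key
    }
  }
  best[3]
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf(
    "Profile model '%s': %d positions, pseudocount %.2g, threshold %s\n",
    x$subgroup_id, nrow(x$emissions), x$pseudocount,
    if (is.na(x$bit_threshold)) "uncalibrated"
    else sprintf("%.2f bits", x$bit_threshold)))
  invisible(x)
}

#' Serialize / restore a profile model as JSON
#'
#' @param model A \code{profile_model}.
#' @param path File path.
#' @export
write_profile_json <- function(model, path) {
  obj <- list(subgroup_id = model$subgroup_id,
              pseudocount = model$pseudocount,
              bit_threshold = model$bit_threshold,
              size = model$size,
              background = as.list(stats::setNames(model$background, AA20)),
              positions = rownames(model$emissions),
              emissions = unname(model$emissions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- obj$emissions
  dimnames(em) <- list(obj$positions, AA20)
  structure(list(emissions = em,
                 background = unlist(obj$background)[AA20],
                 pseudocount = obj$pseudocount,
                 bit_threshold = if (is.null(obj$bit_threshold))
                   NA_real_ else obj$bit_threshold,
                 subgroup_id = obj$subgroup_id,
                 size = obj$size),
            class = "profile_model")
}
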