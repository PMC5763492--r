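#' Pearson chi-squared statistic of a contingency table
#'
#' Sum over cells of (observed - expected)^2 / expected with expected counts
#' taken from the table margins. Cells whose expected count is zero (an
#' entirely empty row or column) contribute nothing, which is equivalent to
#' collapsing those rows/columns.
#'
#' @param tab Numeric matrix of non-negative counts (here 5 x 5 group
#'   co-occurrence counts).
#' @return The chi-squared statistic (>= 0).
#' @export
chi_squared_stat <- function(tab) {
  tot <- sum(tab)
  if (tot <= 0) stop("empty contingency table", call. = FALSE)
  E <- outer(rowSums(tab), colSums(tab)) / tot
  ok <- E > 0
  sum((tab[ok] - E[ok])^2 / E[ok])
}

#' Significance of a positional dependence
#'
#' A chi-squared value marks two window positions as dependent when it
#' strictly exceeds the threshold. The default 34.3 is the upper 0.005
#' critical value of the chi-squared distribution at
#' (5-1) x (5-1) = 16 degrees of freedom, rounded to one decimal.
#'
#' @param chi2 Chi-squared statistic (>= 0).
#' @param threshold Significance cut-off (default 34.3).
#' @return Logical.
#' @export
is_significant <- function(chi2, threshold = 34.3) {
  chi2 > threshold
}

# Map a window character matrix to group indices (NA for the dummy symbol).
group_index_matrix <- function(windows, group_map) {
  check_group_map(group_map)
  m <- window_matrix(windows)
  g <- matrix(group_map[m], nrow(m), ncol(m))
  g
}

# 5 x 5 co-occurrence counts of groups at two columns; sequences with a
# dummy at either position are skipped.
group_contingency <- function(g, i, j) {
  gi <- g[, i]; gj <- g[, j]
  ok <- !is.na(gi) & !is.na(gj)
  counts <- tabulate(5L * (gi[ok] - 1L) + gj[ok], nbins = 25L)
  matrix(counts, 5L, 5L, byrow = TRUE)
}

# Consensus group at position i: the most frequent group among the
# sequences counted in the table (ties to the smaller group index). The
# binary split follows the consensus at the dependent position, which is
# robust to the sparse-cell noise that dominates raw chi-squared cell
# contributions.
dominant_group_of <- function(tab) {
  which.max(rowSums(tab))
}

#' Scan all position pairs for group dependence
#'
#' Computes the chi-squared dependence of amino-acid group occurrence for
#' every ordered pair of window positions, excluding the centre (which is
#' constant within a residue type). Sequences with a dummy at either
#' position of a pair are skipped for that pair.
#'
#' @param windows Character vector of equal-length positive site windows.
#' @param group_map Amino-acid group map (see \code{\link{default_group_map}}).
#' @param threshold Significance cut-off for the \code{significant} flag.
#' @return Data frame with one row per ordered pair: \code{position_i},
#'   \code{position_j} (signed offsets), \code{chi2}, \code{significant},
#'   \code{dominant_group} (group index at \code{position_i}).
#' @export
scan_dependencies <- function(windows, group_map = default_group_map(),
                              threshold = 34.3) {
  if (length(windows) < 2L)
    stop("need at least two fragments to scan dependencies", call. = FALSE)
  g <- group_index_matrix(windows, group_map)
  offs <- window_offsets(ncol(g))
  cols <- which(offs != 0L)
  res <- vector("list", length(cols) * (length(cols) - 1L))
  k <- 0L
  for (i in cols) for (j in cols) {
    if (i == j) next
    tab <- group_contingency(g, i, j)
    chi2 <- if (sum(tab) > 0) chi_squared_stat(tab) else 0
    dom <- if (sum(tab) > 0) dominant_group_of(tab) else NA_integer_
    k <- k + 1L
    res[[k]] <- data.frame(position_i = offs[i], position_j = offs[j],
                           chi2 = chi2,
                           significant = is_significant(chi2, threshold),
                           dominant_group = dom)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Choose the maximal-dependence split of a fragment set
#'
#' Picks the position pair with the largest chi-squared dependence; if it is
#' not significant, returns \code{NULL} (no split). Otherwise partitions the
#' fragments on the first position of that pair into those whose residue
#' belongs to the consensus (most frequent) biochemical group at that
#' position and the rest. Ties on
#' chi-squared are broken by smaller |offset| of the split position, then
#' upstream (negative) before downstream, then smaller group index. With
#' \code{criterion = "sum"} the split position instead maximises the summed
#' chi-squared over all partner positions (the pair used for the dominant
#' group is that position's strongest partner).
#'
#' @param windows Positive site windows of one node.
#' @param group_map Amino-acid group map.
#' @param threshold Chi-squared significance cut-off.
#' @param criterion \code{"pair"} (default) or \code{"sum"}.
#' @return \code{NULL}, or a list with \code{split_position} (signed
#'   offset), \code{split_group} (index), \code{split_group_name},
#'   \code{chi2}, and logical \code{in_group} membership vector.
#' @export
split_node <- function(windows, group_map = default_group_map(),
                       threshold = 34.3, criterion = c("pair", "sum")) {
  criterion <- match.arg(criterion)
  deps <- scan_dependencies(windows, group_map, threshold)
  if (!any(deps$significant)) return(NULL)

  if (criterion == "pair") {
    ord <- order(-deps$chi2, abs(deps$position_i), deps$position_i > 0,
                 deps$dominant_group)
    best <- deps[ord[1L], ]
  } else {
    sums <- tapply(deps$chi2, deps$position_i, sum)
    best_pos <- as.integer(names(sums)[order(-sums, abs(as.integer(names(sums))),
                                             as.integer(names(sums)) > 0)[1L]])
    cand <- deps[deps$position_i == best_pos, ]
    best <- cand[order(-cand$chi2, abs(cand$position_j))[1L], ]
  }

  g <- group_index_matrix(windows, group_map)
  offs <- window_offsets(ncol(g))
  col <- which(offs == best$position_i)
  in_group <- !is.na(g[, col]) & g[, col] == best$dominant_group
  group_names <- attr(group_map, "groups")
  list(split_position = best$position_i,
       split_group = as.integer(best$dominant_group),
       split_group_name = if (!is.null(group_names))
         group_names[[best$dominant_group]] else as.character(best$dominant_group),
       chi2 = best$chi2,
       in_group = in_group)
}

#' Maximal dependence decomposition of positive site windows
#'
#' Recursively partitions the positive fragments into motif subgroups. A
#' node is split only when it holds at least \code{max_cluster_size}
#' members and some position pair shows significant chi-squared dependence;
#' otherwise it becomes a leaf. The in-group child (fragments carrying the
#' dominant group at the split position) is explored first, and leaves are
#' numbered depth-first.
#'
#' @param windows Character vector of positive site windows.
#' @param group_map Amino-acid group map.
#' @param threshold Chi-squared significance cut-off (default 34.3).
#' @param max_cluster_size Minimum node size eligible for splitting
#'   (default 30): subgroups smaller than this are never divided further.
#' @param criterion Split-position criterion, see \code{\link{split_node}}.
#' @param leaf_prefix Prefix for depth-first leaf identifiers.
#' @return An \code{mdd_tree}: list with the recursive \code{root} node,
#'   \code{leaves} (list of leaf nodes with \code{id} and \code{members},
#'   indices into \code{windows}), and the call parameters.
#' @export
mdd_cluster <- function(windows, group_map = default_group_map(),
                        threshold = 34.3, max_cluster_size = 30L,
                        criterion = c("pair", "sum"),
                        leaf_prefix = "grp") {
  criterion <- match.arg(criterion)
  if (!length(windows)) stop("no positive fragments to cluster", call. = FALSE)

  leaf_counter <- 0L
  leaves <- list()

  grow <- function(members) {
    node <- list(members = members, is_leaf = TRUE)
    if (length(members) >= max_cluster_size && length(members) >= 2L) {
      sp <- split_node(windows[members], group_map, threshold, criterion)
      if (!is.null(sp) && any(sp$in_group) && !all(sp$in_group)) {
        node$is_leaf <- FALSE
        node$split_position <- sp$split_position
        node$split_group <- sp$split_group
        node$split_group_name <- sp$split_group_name
        node$chi2 <- sp$chi2
        node$children <- list(
          in_group = grow(members[sp$in_group]),
          out_group = grow(members[!sp$in_group])
        )
        return(node)
      }
    }
    leaf_counter <<- leaf_counter + 1L
    node$id <- paste0(leaf_prefix, "_", leaf_counter)
    leaves[[leaf_counter]] <<- list(id = node$id, members = members)
    node
  }

  root <- grow(seq_along(windows))
  structure(list(root = root, leaves = leaves, windows = windows,
                 threshold = threshold,
                 max_cluster_size = as.integer(max_cluster_size),
                 criterion = criterion, group_map = group_map),
            class = "mdd_tree")
}

#' @export
print.mdd_tree <- function(x, ...) {
  cat(sprintf("Maximal dependence decomposition: %d fragments, %d subgroup%s\n",
              length(x$windows), length(x$leaves),
              if (length(x$leaves) == 1L) "" else "s"))
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$is_leaf) {
      cat(sprintf("%s%s: %d members\n", pad, node$id, length(node$members)))
    } else {
      cat(sprintf("%ssplit at %+d on %s (chi2 = %.1f)\n", pad,
                  node$split_position, node$split_group_name, node$chi2))
      rec(node$children$in_group, indent + 1L)
      rec(node$children$out_group, indent + 1L)
    }
  }
  rec(x$root, 1L)
  invisible(x)
}

#' Position-by-residue count matrix of a fragment set
#'
#' Raw counts per window position suitable for sequence-logo tools
#' (positions as rows, residues as columns). Dummy padding is not counted,
#' so each row sums to the number of fragments minus the dummies at that
#' position.
#'
#' @param windows Character vector of equal-length windows.
#' @return Integer matrix, rows named by signed offset, 20 residue columns.
#' @export
export_logo_counts <- function(windows) {
  if (!length(windows)) stop("empty node", call. = FALSE)
  m <- window_matrix(windows)
  offs <- window_offsets(ncol(m))
  out <- matrix(0L, ncol(m), 20L,
                dimnames = list(sprintf("%+d", offs), AA20))
  for (p in seq_len(ncol(m))) {
    tab <- table(factor(m[, p], levels = AA20))
    out[p, ] <- as.integer(tab)
  }
  out
}
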