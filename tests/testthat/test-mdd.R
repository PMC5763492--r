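test_that("chi-squared statistic matches hand-worked tables", {
  expect_equal(chi_squared_stat(matrix(4, 5, 5)), 0)
  expect_equal(chi_squared_stat(diag(c(10, 10, 0, 0, 0))), 20)
  expect_error(chi_squared_stat(matrix(0, 5, 5)), "empty")
})

test_that("chi-squared agrees with the textbook Pearson computation", {
  set.seed(99)
  for (i in 1:200) {
    repeat {
      tab <- matrix(rpois(25L, 3), 5L, 5L)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(chi_squared_stat(tab),
                 unname(suppressWarnings(
                   stats::chisq.test(tab, correct = FALSE))$statistic),
                 tolerance = 1e-9)
  }
  # an empty row/column contributes nothing (equivalent to collapsing it)
  tab <- matrix(rpois(25L, 4) + 1L, 5L, 5L)
  tab[2L, ] <- 0L
  expect_equal(chi_squared_stat(tab),
               chi_squared_stat(tab[-2L, , drop = FALSE]))
})

test_that("the 34.3 cut-off is the 16-df upper 0.005 critical value", {
  expect_equal(round(stats::qchisq(0.995, df = 16), 1), 34.3)
  expect_true(is_significant(35.0))
  expect_false(is_significant(34.3))   # strict inequality
  expect_false(is_significant(0))
})

test_that("dependence scan covers all ordered non-centre pairs", {
  w <- random_windows(30L, n = 4L, seed = 31L)
  deps <- scan_dependencies(w)
  expect_equal(nrow(deps), 8L * 7L)
  expect_false(any(deps$position_i == 0L | deps$position_j == 0L))
  expect_true(all(deps$chi2 >= 0))
  # chi-squared is symmetric in the pair
  key <- paste(pmin(deps$position_i, deps$position_j),
               pmax(deps$position_i, deps$position_j))
  expect_lt(max(tapply(deps$chi2, key, function(x) diff(range(x)))), 1e-9)

  ident <- rep(strrep("K", 9L), 10L)
  deps2 <- scan_dependencies(ident)
  expect_equal(deps2$chi2, rep(0, nrow(deps2)))
})

test_that("a planted co-occurring motif attains the maximal dependence", {
  sf <- synth_fragments(200L, 0L, seed = 44L)   # basic at -3 with partner +8
  deps <- scan_dependencies(sf$positives)
  best <- deps[which.max(deps$chi2), ]
  expect_true(all(sort(c(best$position_i, best$position_j)) == c(-3L, 8L)))
  expect_true(best$significant)
})

test_that("split_node partitions on the consensus group of the best pair", {
  sf <- synth_fragments(200L, 0L, seed = 7L)
  sp <- split_node(sf$positives)
  expect_equal(sp$split_position, -3L)
  expect_equal(sp$split_group_name, "basic")
  expect_true(any(sp$in_group) && !all(sp$in_group))
  # in-group members all carry the group; out-group none do
  gm <- default_group_map()
  at3 <- substr(sf$positives, 8L, 8L)
  carriers <- !is.na(gm[at3]) & gm[at3] == 3L
  expect_equal(sp$in_group, unname(carriers))

  # identical fragments have zero dependence everywhere: no split
  expect_null(split_node(rep(strrep("K", 21L), 40L)))
})

test_that("planted 60%-penetrance motifs are recovered across replicates", {
  hits <- 0L
  recovered <- numeric(0)
  for (s in 1:20) {
    sf <- synth_fragments(200L, 0L,
                          motifs = list(motif_spec(-3L, c("K", "R", "H"),
                                                   penetrance = 0.6,
                                                   co_position = 8L)),
                          seed = 400L + s)
    sp <- split_node(sf$positives)
    if (!is.null(sp) && sp$split_position == -3L && sp$split_group == 3L) {
      hits <- hits + 1L
      planted <- substr(sf$positives, 8L, 8L) %in% c("K", "R", "H")
      recovered <- c(recovered, sum(sp$in_group & planted) / sum(planted))
    }
  }
  expect_gte(hits, 19L)
  expect_true(all(recovered >= 0.95))
})

test_that("mdd_cluster terminates and conserves its members", {
  w <- random_windows(20L, seed = 15L)
  tr <- mdd_cluster(w, max_cluster_size = 30L)
  expect_length(tr$leaves, 1L)   # below max-cluster-size: never divided

  sf <- synth_fragments(240L, 0L,
                        motifs = list(motif_spec(-3L, c("K", "R"), 0.95, 8L),
                                      motif_spec(2L, c("D", "E"), 0.95, -6L)),
                        seed = 10L)
  tr2 <- mdd_cluster(sf$positives, leaf_prefix = "CarbK")
  members <- unlist(lapply(tr2$leaves, `[[`, "members"))
  expect_equal(sort(members), seq_along(sf$positives))   # exact partition
  expect_equal(vapply(tr2$leaves, `[[`, character(1), "id"),
               paste0("CarbK_", seq_along(tr2$leaves)))
  expect_gte(length(tr2$leaves), 2L)

  # determinism
  tr3 <- mdd_cluster(sf$positives, leaf_prefix = "CarbK")
  expect_identical(tr2$root, tr3$root)

  expect_output(print(tr2), "split at")
})

test_that("logo count matrices conserve counts across the partition", {
  single <- export_logo_counts(strrep("A", 5L))
  expect_equal(unname(single[, "A"]), rep(1L, 5L))
  expect_equal(sum(single), 5L)

  sf <- synth_fragments(150L, 0L, seed = 3L)
  tr <- mdd_cluster(sf$positives)
  root_counts <- export_logo_counts(sf$positives)
  leaf_sum <- Reduce(`+`, lapply(tr$leaves, function(l)
    export_logo_counts(sf$positives[l$members])))
  expect_equal(leaf_sum, root_counts)
  expect_equal(unname(rowSums(root_counts)), rep(150L, 21L))

  # TSV export consumable by logo tools
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(root_counts, tmp, sep = "\t", quote = FALSE)
  back <- as.matrix(utils::read.delim(tmp, row.names = 1L,
                                      check.names = FALSE))
  expect_equal(unname(back), unname(root_counts))
})
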