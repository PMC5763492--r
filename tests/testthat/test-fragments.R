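test_that("extract_fragment pads termini with dummies and preserves length", {
  prot12 <- paste(rep("ACDEFGHIKLMN", 1L), collapse = "")  # length 12
  w <- extract_fragment(prot12, 5L, n = 10L)
  expect_equal(nchar(w), 21L)
  expect_equal(substr(w, 1L, 6L), "------")
  expect_equal(substr(w, 7L, 18L), prot12)
  expect_equal(substr(w, 19L, 21L), "---")

  prot21 <- random_windows(1L, seed = 3L)
  w2 <- extract_fragment(prot21, 11L, n = 10L)
  expect_equal(w2, prot21)   # window equals the whole protein, no padding

  expect_error(extract_fragment("ACDK", 9L, n = 2L, id = "px"), "px")
  expect_error(extract_fragment("ACDK", 0L, n = 2L), "position")
})

test_that("windows are length 2n+1 and round-trip to the source protein", {
  set.seed(41)
  for (i in 1:25) {
    len <- sample(5:60, 1L)
    n <- sample(1:12, 1L)
    prot <- paste(sample(carbmotif:::AA20, len, TRUE), collapse = "")
    pos <- sample(len, 1L)
    w <- extract_fragment(prot, pos, n)
    expect_equal(nchar(w), 2L * n + 1L)
    chars <- strsplit(w, "")[[1]]
    nd <- which(chars != "-")
    # dummies only as contiguous prefix/suffix
    expect_true(all(diff(nd) == 1L))
    expect_equal(paste(chars[nd], collapse = ""),
                 substr(prot, max(1L, pos - n), min(len, pos + n)))
    expect_equal(chars[n + 1L], substr(prot, pos, pos))
  }
})

test_that("build_candidate_sites enumerates non-annotated residues as negatives", {
  proteins <- c(p1 = "KAKAK")
  sites <- data.frame(protein_id = "p1", position = 1L, residue = "K",
                      label = "positive", stringsAsFactors = FALSE)
  ds <- build_candidate_sites(proteins, sites, "K", n = 2L)
  expect_equal(nrow(ds$positives), 1L)
  expect_equal(sort(ds$negatives$position), c(3L, 5L))
  expect_false(any(duplicated(paste(ds$negatives$protein_id,
                                    ds$negatives$position))))

  no_k <- c(p2 = "AGGA")
  ds2 <- build_candidate_sites(no_k, sites[0, ], "K", n = 2L)
  expect_equal(nrow(ds2$positives), 0L)
  expect_equal(nrow(ds2$negatives), 0L)

  bad <- data.frame(protein_id = "p1", position = 2L, residue = "K",
                    label = "positive", stringsAsFactors = FALSE)
  expect_error(build_candidate_sites(proteins, bad, "K"), "p1")
})

test_that("redundancy reduction matches a brute-force greedy filter", {
  w <- random_windows(100L, seed = 17L)
  # force some near-duplicates
  w[13] <- w[2]
  substr(w[40], 1, 10) <- substr(w[7], 1, 10)
  keep <- redundancy_keep(w, 0.5)

  ident <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    ok <- ca != "-" & cb != "-"
    if (!any(ok)) return(0)
    sum(ca[ok] == cb[ok]) / sum(ok)
  }
  oracle <- logical(length(w))
  retained <- character(0)
  for (i in seq_along(w)) {
    sim <- any(vapply(retained, function(r) ident(w[i], r) >= 0.5, logical(1)))
    oracle[i] <- !sim
    if (!sim) retained <- c(retained, w[i])
  }
  expect_equal(keep, oracle)
  expect_false(keep[13])

  # idempotence
  kept <- w[keep]
  expect_true(all(redundancy_keep(kept, 0.5)))
})

test_that("redundancy reduction handles edge cases and references", {
  a <- strrep("A", 21)
  b <- paste(rep(c("C", "D"), length.out = 21), collapse = "")
  expect_equal(redundancy_keep(c(a, a), 0.5), c(TRUE, FALSE))
  expect_equal(redundancy_keep(c(a, b), 0.5), c(TRUE, TRUE))
  # a fragment similar to the reference set is dropped even if novel here
  expect_equal(redundancy_keep(b, 0.5, reference = b), FALSE)
  expect_error(redundancy_keep(c(a, "AC"), 0.5), "length")
  expect_error(redundancy_keep(a, 0), "identity_threshold")
})

test_that("negative sampling hits the 2:1 ratio reproducibly", {
  pool <- random_windows(1200L, seed = 5L)
  for (np in c(256L, 115L)) {
    ds <- windows_to_dataset(random_windows(np, seed = np), pool)
    out <- sample_negatives(ds, 2L, seed = 9L)
    expect_equal(nrow(out$negatives), 2L * np)
    expect_true(all(out$negatives$window %in% pool))
    again <- sample_negatives(ds, 2L, seed = 9L)
    expect_identical(out$negatives, again$negatives)
    other <- sample_negatives(ds, 2L, seed = 10L)
    expect_false(identical(out$negatives, other$negatives))
  }
  tiny <- windows_to_dataset(random_windows(10L, seed = 2L),
                             random_windows(5L, seed = 3L))
  expect_error(sample_negatives(tiny, 2L, 1L), "short")
})

test_that("FASTA and site/fragment tables round-trip through disk", {
  syn <- synth_proteins(n_proteins = 4L, n_positive_sites = 8L, seed = 21L)
  dir <- withr::local_tempdir()
  paths <- write_synth(syn, dir)
  prot <- read_protein_fasta(paths[["fasta"]])
  expect_identical(prot, syn$proteins)
  sites <- read_site_table(paths[["sites"]])
  expect_equal(sites$position, syn$sites$position)
  expect_true(all(mapply(function(pid, p)
    substr(prot[[pid]], p, p) == "K", sites$protein_id, sites$position)))

  ds <- build_candidate_sites(prot, sites, "K")
  f <- file.path(dir, "frags.tsv")
  write_fragments(ds$positives, f)
  back <- read_fragments(f)
  expect_equal(back$window, ds$positives$window)
  expect_equal(back$position, ds$positives$position)
})
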