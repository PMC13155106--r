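test_that("global identity reproduces worked examples and is symmetric", {
  expect_identical(global_identity("ACGT", "ACGT"), 1)
  expect_identical(global_identity("ACGT", "ACGA"), 0.75)
  # one gap column, 7 matching columns over alignment length 8
  expect_identical(global_identity("ACGTACGT", "ACGTCGT"), 0.875)
  expect_identical(global_identity("ACGTCGT", "ACGTACGT"), 0.875)
  expect_error(global_identity("", "ACGT"), "nonempty")
})

test_that("global identity agrees with the independent DP oracle", {
  set.seed(101)
  for (k in 1:60) {
    a <- rand_dna_seq(sample(5:60, 1))
    b <- if (k %% 3 == 0) mutate_positions(a, sample(nchar(a), 2)) else
      rand_dna_seq(sample(5:60, 1))
    o <- nw_oracle(a, b)
    expect_equal(global_identity(a, b), o$identity, tolerance = 1e-12)
    expect_equal(global_identity(b, a), o$identity, tolerance = 1e-12)
  }
})

make_asvs <- function(ids, seqs, totals) {
  counts <- matrix(totals, ncol = 1, dimnames = list(ids, "s1"))
  asv_set(ids, seqs, counts)
}

test_that("clustering handles singletons, identical sequences and planted clusters", {
  one <- cluster_asvs(make_asvs("a1", "ACGTACGTAA", 5))
  expect_equal(nrow(one$otu), 1L)
  expect_equal(unname(one$membership[["a1"]]), one$otu$id[1])

  dup <- cluster_asvs(make_asvs(c("a1", "a2"), rep("ACGTACGTAA", 2), c(5, 3)))
  expect_equal(nrow(dup$otu), 1L)

  # three planted clusters: within >= 0.98, between <= 0.90
  set.seed(7)
  between_max <- function(b) max(global_identity(b[1], b[2]),
                                 global_identity(b[1], b[3]),
                                 global_identity(b[2], b[3]))
  base <- replicate(3, rand_dna_seq(100))
  while (between_max(base) > 0.90) base <- replicate(3, rand_dna_seq(100))
  ids <- sprintf("a%02d", 1:12)
  seqs <- unlist(lapply(base, function(b) {
    c(b, vapply(1:3, function(k) mutate_positions(b, sample(100, 2)), ""))
  }))
  totals <- rev(seq_along(ids)) * 10
  res <- cluster_asvs(make_asvs(ids, seqs, totals), threshold = 0.97)
  expect_equal(nrow(res$otu), 3L)
  oracle <- cluster_oracle(ids, seqs, totals)
  expect_identical(partition_sets(ids, res$membership[ids]),
                   partition_sets(ids, oracle))

  expect_error(cluster_asvs(make_asvs(c("x", "x"), c("ACGT", "ACGT"), c(1, 1))),
               "duplicate")
})

test_that("every cluster member meets the identity threshold to its centroid", {
  set.seed(21)
  ids <- sprintf("a%02d", 1:20)
  base <- replicate(4, rand_dna_seq(80))
  seqs <- vapply(seq_along(ids), function(i) {
    mutate_positions(base[(i %% 4) + 1], sample(80, sample(0:2, 1)))
  }, "")
  asvs <- make_asvs(ids, seqs, sample(100, 20))
  res <- cluster_asvs(asvs, threshold = 0.97)
  for (g in res$otu$id) {
    members <- names(res$membership)[res$membership == g]
    cent <- res$rep_sequences[[g]] # representative equals centroid here
    for (mid in members) {
      expect_gte(global_identity(asvs$sequences[match(mid, asvs$ids)], cent),
                 0.97)
    }
  }
})

test_that("clustering is invariant to input order of equal-abundance ASVs", {
  set.seed(5)
  base <- rand_dna_seq(60)
  other <- rand_dna_seq(60)
  ids <- sprintf("a%d", 1:6)
  seqs <- c(base, mutate_positions(base, 1), other,
            mutate_positions(other, 2), base, other)
  counts <- matrix(rep(10, 6), ncol = 1, dimnames = list(ids, "s1"))
  a1 <- asv_set(ids, seqs, counts)
  perm <- c(4, 1, 6, 2, 5, 3)
  a2 <- asv_set(ids[perm], seqs[perm], counts[perm, , drop = FALSE])
  r1 <- cluster_asvs(a1)
  r2 <- cluster_asvs(a2)
  expect_identical(partition_sets(ids, r1$membership[ids]),
                   partition_sets(ids, r2$membership[ids]))
})

test_that("representative selection follows reads then sequence then id", {
  asvs <- make_asvs(c("a", "b"), c("GGGG", "AAAA"), c(10, 5))
  expect_identical(pick_representative(c("a", "b"), asvs), "a")
  tie <- make_asvs(c("a", "b"), c("CCCC", "AAAA"), c(7, 7))
  expect_identical(pick_representative(c("a", "b"), tie), "b")
  expect_identical(pick_representative("a", asvs), "a")
  expect_error(pick_representative(character(0), asvs), "empty")
})

test_that("rare-OTU filter uses the pre-filter grand total and boundaries", {
  ids <- c("big", "keep", "drop")
  seqs <- c(rand_dna_seq(50), rand_dna_seq(50), rand_dna_seq(50))
  counts <- matrix(c(999901, 50, 49), ncol = 1, dimnames = list(ids, "s1"))
  asvs <- asv_set(ids, seqs, counts)
  otus <- cluster_asvs(asvs, threshold = 1.01) # force singleton OTUs
  expect_equal(nrow(otus$otu), 3L)
  filt <- filter_rare(otus, min_fraction = 0.00005)
  kept <- otus$otu$id[match(c("big", "keep"), otus$otu$representative)]
  expect_setequal(filt$otu$representative, c("big", "keep"))
  expect_identical(filter_rare(otus, min_fraction = 0)$otu$id, otus$otu$id)
  expect_equal(sum(filt$counts), 999951)
  strict <- filter_rare(otus, min_fraction = 0.5)
  expect_equal(nrow(strict$otu), 1L)
  zero <- otus
  zero$counts[] <- 0
  expect_error(filter_rare(zero), "all-zero")
})

test_that("ASV container rejects bad input", {
  expect_error(asv_set("a", "ACGN", matrix(1)), "alphabet")
  expect_error(asv_set("a", "", matrix(1)), "empty")
  expect_error(asv_set(c("a", "a"), c("ACGT", "ACGT"), matrix(1:2)), "duplicate")
  expect_error(asv_set("a", "ACGT", matrix(-1)), "negative")
})

test_that("FASTA round trip preserves ids and sequences", {
  asvs <- make_asvs(c("a1", "a2"), c("ACGTAC", "TTGGCC"), c(3, 4))
  p <- withr::local_tempfile(fileext = ".fasta")
  write_asv_fasta(asvs, p)
  back <- read_fasta(p)
  expect_identical(back, setNames(asvs$sequences, asvs$ids))
})
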