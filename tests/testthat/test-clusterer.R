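test_that("dereplication collapses exact duplicates and conserves counts", {
  records <- data.frame(sample_id = c("S1", "S1", "S2"),
                        sequence = c("ACGT", "ACGT", "ACGT"))
  u <- dereplicate(records)
  expect_equal(u$sequence, "ACGT")
  expect_equal(u$counts[1, ], c(S1 = 2L, S2 = 1L))

  empty <- dereplicate(records[0, ])
  expect_length(empty$sequence, 0L)

  set.seed(21)
  planted <- rand_dna(3, 30)
  n <- c(500, 300, 200)
  big <- data.frame(sample_id = sample(c("A", "B"), 1000, replace = TRUE),
                    sequence = rep(planted, n))
  u2 <- dereplicate(big)
  expect_equal(sort(as.integer(rowSums(u2$counts))), sort(n))
  expect_equal(sum(u2$counts), 1000L)
})

test_that("pairwise identity follows the max-match global alignment definition", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAG"), 0.9)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  # symmetry
  set.seed(22)
  a <- rand_dna(20, sample(25:45, 20, replace = TRUE))
  b <- rand_dna(20, sample(25:45, 20, replace = TRUE))
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # a deletion costs one column: 39 matches over 40 columns
  s <- rand_dna(1, 40)
  expect_equal(pairwise_identity(s, paste0(substr(s, 1, 19), substr(s, 21, 40))),
               39 / 40)
})

test_that("identity exactly at the threshold joins the cluster", {
  a <- "ACGTACGTAC"
  b <- "ACGTACGTAG"   # identity 0.9
  uniq <- list(sequence = c(a, b),
               counts = matrix(c(5L, 3L), 2, 1, dimnames = list(NULL, "S1")))
  ct <- cluster_pool(uniq, identity_threshold = 0.90)
  expect_equal(nrow(ct$clusters), 1L)
  expect_equal(ct$clusters$representative, a)
  expect_equal(ct$clusters$total, 8L)
  ct2 <- cluster_pool(uniq, identity_threshold = 0.91)
  expect_equal(nrow(ct2$clusters), 2L)
})

test_that("a planted family of one-mutation variants forms a single cluster", {
  set.seed(23)
  master <- rand_dna(1, 40)
  vars <- vapply(1:12, function(i) {
    s <- strsplit(master, "")[[1]]
    s[i] <- setdiff(c("A", "C", "G", "T"), s[i])[1]
    paste(s, collapse = "")
  }, character(1))
  records <- data.frame(
    sample_id = "S1",
    sequence = c(rep(master, 50), rep(vars, times = 2)))
  ct <- cluster_pool(dereplicate(records))
  expect_equal(nrow(ct$clusters), 1L)
  expect_equal(ct$clusters$total, 74L)
  expect_equal(ct$clusters$representative, master)
  expect_equal(ct$clusters$rep_exact_total, 50L)
})

test_that("greedy clustering matches the brute-force oracle", {
  set.seed(24)
  # mixture of related families and unrelated sequences, random counts
  masters <- rand_dna(8, 36)
  seqs <- unlist(lapply(masters, function(m) {
    c(m, vapply(1:6, function(i) {
      s <- strsplit(m, "")[[1]]
      pos <- sample(36, sample(1:4, 1))
      for (p in pos) s[p] <- sample(setdiff(c("A","C","G","T"), s[p]), 1)
      paste(s, collapse = "")
    }, character(1)))
  }))
  seqs <- unique(c(seqs, rand_dna(30, sample(25:45, 30, replace = TRUE))))
  counts <- matrix(sample(1:50, 2 * length(seqs), replace = TRUE),
                   ncol = 2, dimnames = list(NULL, c("A", "B")))
  uniq <- list(sequence = seqs, counts = counts)
  for (thr in c(0.85, 0.90)) {
    got <- cluster_pool(uniq, identity_threshold = thr)
    want <- oracle_cluster_table(uniq, thr)
    expect_equal(got$clusters$representative, want$representative)
    expect_equal(unname(got$copies), unname(want$copies))
  }
})

test_that("clustering is deterministic and invariant to input order", {
  set.seed(25)
  seqs <- unique(rand_dna(60, sample(25:45, 60, replace = TRUE)))
  counts <- matrix(sample(1:20, length(seqs), replace = TRUE),
                   ncol = 1, dimnames = list(NULL, "S"))
  uniq <- list(sequence = seqs, counts = counts)
  perm <- sample(length(seqs))
  uniq_perm <- list(sequence = seqs[perm],
                    counts = counts[perm, , drop = FALSE])
  expect_identical(cluster_pool(uniq), cluster_pool(uniq))
  expect_identical(cluster_pool(uniq), cluster_pool(uniq_perm))
})

test_that("raising the identity threshold never decreases the cluster count", {
  set.seed(26)
  masters <- rand_dna(5, 32)
  seqs <- unique(c(unlist(lapply(masters, function(m) {
    vapply(1:8, function(i) {
      s <- strsplit(m, "")[[1]]
      pos <- sample(32, sample(1:5, 1))
      for (p in pos) s[p] <- sample(setdiff(c("A","C","G","T"), s[p]), 1)
      paste(s, collapse = "")
    }, character(1))
  })), rand_dna(20, 32)))
  uniq <- list(sequence = seqs,
               counts = matrix(rep(1L, length(seqs)), ncol = 1,
                               dimnames = list(NULL, "S")))
  ncl <- vapply(c(0.75, 0.85, 0.9, 0.95, 1.0), function(thr)
    nrow(cluster_pool(uniq, identity_threshold = thr)$clusters), numeric(1))
  expect_true(all(diff(ncl) >= 0))
})

test_that("cluster copies conserve retained records per sample", {
  set.seed(27)
  records <- data.frame(
    sample_id = sample(c("S1", "S2", "S3"), 800, replace = TRUE),
    sequence = sample(rand_dna(40, 30), 800, replace = TRUE))
  ct <- cluster_pool(dereplicate(records))
  expect_equal(colSums(ct$copies)[names(ct$sample_totals)],
               ct$sample_totals)
  expect_equal(unname(ct$sample_totals[c("S1", "S2", "S3")]),
               as.integer(table(records$sample_id)[c("S1", "S2", "S3")]))
})

test_that("cluster tables round-trip through TSV", {
  set.seed(28)
  records <- data.frame(sample_id = rep(c("S1", "S2"), 50),
                        sequence = sample(rand_dna(10, 28), 100, replace = TRUE))
  ct <- cluster_pool(dereplicate(records))
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fasta")
  write_clusters(ct, tsv, fasta = fa)
  back <- read_clusters(tsv)
  expect_equal(back$clusters$cluster_id, ct$clusters$cluster_id)
  expect_equal(back$copies, ct$copies)
  expect_equal(back$sample_totals, ct$sample_totals)
  reps <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(reps), stats::setNames(ct$clusters$representative,
                                                   ct$clusters$cluster_id))
})
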