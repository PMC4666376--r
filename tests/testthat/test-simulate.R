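# minimal hand-built pool/model pair for the selection-model unit checks
fake_pool <- function(freqs, seqs = NULL) {
  n <- length(freqs)
  structure(list(
    members = data.frame(sequence = seqs %||% rand_dna(n, 30),
                         frequency = freqs,
                         family_id = "background",
                         stringsAsFactors = FALSE),
    families = list(), design = default_library_design(),
    identity_threshold = 0.9),
    class = "truth_pool")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

fake_model <- function(a, background = 0) {
  structure(list(a = a, background_retention = background,
                 panel = character()),
            class = "affinity_model")
}

test_that("the truth pool is frequency-normalised and deterministic", {
  pool <- truth_pool(seed = 61)
  expect_equal(nrow(pool$members), 5 * 20 + 1000)
  expect_equal(sum(pool$members$frequency), 1, tolerance = 1e-12)
  expect_false(anyDuplicated(pool$members$sequence) > 0)
  pool2 <- truth_pool(seed = 61)
  expect_identical(pool$members, pool2$members)
  expect_false(identical(pool$members, truth_pool(seed = 62)$members))
})

test_that("family members stay within the identity threshold of their master", {
  pool <- truth_pool(seed = 63)
  for (fid in names(pool$families)) {
    master <- pool$families[[fid]]$master
    members <- pool$members$sequence[pool$members$family_id == fid]
    ids <- pairwise_identity(members, master)
    expect_true(all(ids >= pool$identity_threshold - 1e-9))
  }
})

test_that("planted motifs are present verbatim in every family member", {
  pool <- truth_pool(seed = 64)
  for (fid in names(pool$families)) {
    fam <- pool$families[[fid]]
    members <- pool$members$sequence[pool$members$family_id == fid]
    for (mot in fam$motifs)
      expect_true(all(grepl(mot, members, fixed = TRUE)))
  }
})

test_that("proportional-capture selection follows the stated formula", {
  # deterministic capture: the only binder takes over
  a <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "wt"))
  pool <- fake_pool(c(0.5, 0.5))
  expect_equal(select_round(pool, fake_model(a, 0), "wt"), c(1, 0))
  # selection-neutral: uniform affinities leave the pool unchanged
  set.seed(65)
  f <- runif(10); f <- f / sum(f)
  au <- matrix(1, 10, 1, dimnames = list(NULL, "wt"))
  expect_equal(select_round(fake_pool(f), fake_model(au, 0.3), "wt"), f)
  # arbitrary pool matches an explicit elementwise normalisation
  a10 <- matrix(runif(10, 0, 3), 10, 1, dimnames = list(NULL, "wt"))
  b <- 0.05
  got <- select_round(fake_pool(f), fake_model(a10, b), "wt")
  want <- numeric(10)
  denom <- 0
  for (j in 1:10) denom <- denom + f[j] * (a10[j, 1] + b)
  for (i in 1:10) want[i] <- f[i] * (a10[i, 1] + b) / denom
  expect_equal(got, want)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_error(select_round(fake_pool(f), fake_model(au * 0, 0), "wt"),
               "zero")
})

test_that("analytic expected EF matches its closed form", {
  f <- c(0.5, 0.5)
  a <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "wt"))
  pool <- fake_pool(f)
  # sum_j f_j a_j = 0.5, so the binder doubles
  expect_equal(expected_ef(pool, fake_model(a, 0), "wt"), c(2, 0))
  expect_equal(expected_ef(pool, fake_model(matrix(1, 2, 1,
                 dimnames = list(NULL, "wt")), 0.2), "wt"), c(1, 1))
  expect_equal(expected_ef(pool, fake_model(a, 0), "input"), c(1, 1))
  # EF is the ratio of post- to pre-selection frequency
  set.seed(66)
  f10 <- runif(10); f10 <- f10 / sum(f10)
  a10 <- matrix(runif(10), 10, 1, dimnames = list(NULL, "wt"))
  m <- fake_model(a10, 0.01)
  p10 <- fake_pool(f10)
  expect_equal(expected_ef(p10, m, "wt"),
               select_round(p10, m, "wt") / f10)
})

test_that("multinomial sampling reproduces frequencies within 3 SE", {
  f <- c(0.5, 0.3, 0.15, 0.04, 0.01)
  n <- 1e5
  counts <- sample_pool_counts(f, n, seed = 67)
  expect_equal(sum(counts), n)
  se <- sqrt(n * f * (1 - f))
  expect_true(all(abs(counts - n * f) <= 3 * se))
})

test_that("error-free reads from a single member reconstruct it exactly", {
  design <- default_library_design()
  member <- rand_dna(1, 38)
  reads <- sim_reads(member, 200L, design, "TACAGT", "GGTAAT",
                     error_rate = 0, seed = 68)
  out <- pair_to_variable(substring(reads$fwd, 7L), substring(reads$rev, 7L),
                          design)
  expect_true(all(out$variable == member))
})

test_that("substitution errors hit individual bases at the requested rate", {
  set.seed(69)
  seqs <- rep(strrep("ACGT", 25), 2000)
  mutated <- branchedselex:::cpp_add_errors(seqs, 0.01)
  nerr <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 seqs[1:500], mutated[1:500])
  rate <- sum(nerr) / (500 * 100)
  expect_gt(rate, 0.005); expect_lt(rate, 0.02)
  expect_equal(nchar(mutated), nchar(seqs))
})

test_that("amplicons too long to merge are a configuration error", {
  design <- library_design("ACGTACGTACGTACGTACGT",
                           "TTGATATAAATAGTGCCCATGGATCCGCGGGTGTCGGG",
                           read_length = 50)
  expect_error(sim_reads(rand_dna(1, 45), 1L, design, "TACAGT", "GGTAAT"),
               "overlap")
})

test_that("FASTQ emission round-trips through the reader, gzipped included", {
  design <- default_library_design()
  reads <- sim_reads(rand_dna(3, 30), c(5L, 3L, 2L), design,
                     "TACAGT", "GGTAAT", error_rate = 0, seed = 70)
  r1 <- tempfile(fileext = ".fastq.gz")
  r2 <- tempfile(fileext = ".fastq.gz")
  write_fastq_pair(reads, r1, r2)
  back <- read_fastq_pair(r1, r2)
  expect_equal(back$fwd, reads$fwd)
  expect_equal(back$rev, reads$rev)
})

test_that("two barcoded samples demultiplex perfectly at zero error rate", {
  design <- default_library_design()
  sheet <- default_sample_sheet()[1:2, ]
  pool <- truth_pool(n_background = 30, family_size = 5, seed = 71)
  model <- affinity_model(pool, seed = 71)
  sim <- sim_branched_experiment(pool, model, sheet, n_reads = 1500,
                                 error_rate = 0, reads = TRUE, seed = 71)
  fwd <- unlist(lapply(sim$reads, `[[`, "fwd"), use.names = FALSE)
  rev_ <- unlist(lapply(sim$reads, `[[`, "rev"), use.names = FALSE)
  dm <- demultiplex(fwd, rev_, sheet)
  expect_equal(unname(dm$assigned), c(1500L, 1500L))
  expect_equal(sum(dm$rejected), 0L)
})

test_that("per-sample seed streams make samples independently reproducible", {
  pool <- truth_pool(n_background = 50, family_size = 5, seed = 72)
  model <- affinity_model(pool, seed = 72)
  sheet <- default_sample_sheet()[1:3, ]
  a <- sim_branched_experiment(pool, model, sheet, n_reads = 1000, seed = 9)
  b <- sim_branched_experiment(pool, model, sheet[c(2, 1, 3), ],
                               n_reads = 1000, seed = 9)
  expect_equal(a$counts[, "input"], b$counts[, "input"])
  expect_identical(a$counts,
                   sim_branched_experiment(pool, model, sheet,
                                           n_reads = 1000, seed = 9)$counts)
})
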