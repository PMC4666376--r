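# shared fixtures, all generated in code

rand_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len[i], replace = TRUE), collapse = ""),
    character(1))
}

# build error-free overlapping read pairs for given variable regions
make_read_pair <- function(var_seqs, design, barcode_fwd = "", barcode_rev = "") {
  amp <- paste0(barcode_fwd, design$fwd_constant, var_seqs,
                design$rev_constant, revcomp(barcode_rev))
  list(fwd = substr(amp, 1, design$read_length),
       rev = substr(revcomp(amp), 1, design$read_length))
}

# hand-assembled cluster table (fixture for the quantify/profiler layers)
make_ct <- function(copies, representative = NULL) {
  if (is.null(representative))
    representative <- rand_dna(nrow(copies), 40)
  structure(list(
    clusters = data.frame(cluster_id = rownames(copies),
                          representative = representative,
                          rep_exact_total = as.integer(rowSums(copies)),
                          total = as.integer(rowSums(copies)),
                          stringsAsFactors = FALSE),
    copies = copies,
    sample_totals = stats::setNames(as.integer(colSums(copies)),
                                    colnames(copies))),
    class = "cluster_table")
}

# counts-level dataset: exact member counts through the quantify layer,
# bypassing read synthesis (no sequencing error)
counts_level_dataset <- function(pool, model, sheet, n_reads, seed) {
  sim <- sim_branched_experiment(pool, model, sheet, n_reads = n_reads,
                                 reads = FALSE, seed = seed)
  uniq <- list(sequence = pool$members$sequence, counts = sim$counts)
  ct <- cluster_pool(uniq, identity_threshold = pool$identity_threshold)
  fr <- pool_fractions(ct)
  et <- enrichment_table(fr, sheet, ct)
  list(ct = ct, fr = fr, et = et, sim = sim)
}

# independent brute-force greedy clustering over exported pairwise_identity
oracle_cluster_table <- function(uniq, threshold) {
  tot <- as.integer(rowSums(uniq$counts))
  ord <- order(-tot, uniq$sequence, method = "radix")
  seqs <- uniq$sequence[ord]
  counts <- uniq$counts[ord, , drop = FALSE]
  cents <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (ci in seq_along(cents)) {
      if (pairwise_identity(seqs[i], seqs[cents[ci]]) >= threshold - 1e-9) {
        hit <- ci; break
      }
    }
    if (hit == 0L) { cents <- c(cents, i); hit <- length(cents) }
    assign[i] <- hit
  }
  copies <- rowsum(counts, assign)
  first <- match(seq_along(cents), assign)
  total <- as.integer(rowSums(copies))
  ord2 <- order(-total, seqs[first], method = "radix")
  list(representative = seqs[first][ord2],
       copies = matrix(as.integer(copies[ord2, ]), ncol = ncol(counts),
                       dimnames = list(NULL, colnames(counts))))
}

sorted_profile <- function(x) paste(sort(x), collapse = ",")

family_truth_profiles <- function(pool) {
  vapply(pool$families, function(f) sorted_profile(f$profile), character(1))
}

# cluster ids of the planted family masters in a cluster table
family_cluster_ids <- function(pool, ct) {
  masters <- vapply(pool$families, `[[`, character(1), "master")
  stats::setNames(ct$clusters$cluster_id[match(masters, ct$clusters$representative)],
                  names(pool$families))
}
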