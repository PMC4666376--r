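#' Collapse exact duplicate sequences into unique sequences with counts
#'
#' Dereplication: one entry per distinct exact sequence, with its copy count
#' partitioned by sample. Counts are conserved: the count matrix sums to the
#' number of input records.
#'
#' @param records data.frame with columns `sample_id` and `sequence`
#'   (variable-region records from [preprocess_run()]).
#' @param samples optional character vector fixing the columns (and their
#'   order) of the count matrix; defaults to the samples present, in order of
#'   first appearance.
#' @return a list with `sequence` (character vector of unique sequences) and
#'   `counts` (integer matrix, unique sequences x samples).
#' @export
dereplicate <- function(records, samples = NULL) {
  if (is.null(samples)) samples <- unique(records$sample_id)
  if (nrow(records) == 0L) {
    return(list(sequence = character(),
                counts = matrix(0L, 0L, length(samples),
                                dimnames = list(NULL, samples))))
  }
  dt <- data.table::data.table(sequence = records$sequence,
                               sample_id = records$sample_id)
  agg <- dt[, .N, by = c("sequence", "sample_id")]
  wide <- data.table::dcast(agg, sequence ~ sample_id, value.var = "N",
                            fill = 0L)
  seqs <- wide$sequence
  miss <- setdiff(samples, colnames(wide))
  for (m in miss) wide[[m]] <- 0L
  counts <- as.matrix(wide[, samples, with = FALSE])
  rownames(counts) <- NULL
  list(sequence = seqs, counts = counts)
}

#' Pairwise sequence identity
#'
#' Fraction of matching columns under a global alignment that maximises the
#' number of matches (match +1, mismatch 0, linear gap 0) and, among such
#' alignments, uses the fewest columns. Symmetric; 1 for identical strings;
#' 0 when no column matches.
#'
#' @param a,b non-empty nucleotide strings (vectorised, recycled).
#' @return numeric vector of identities in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGTACGTAG") # 0.9
#' @export
pairwise_identity <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("sequences must be non-empty")
  mapply(cpp_pairwise_identity, as.character(a), as.character(b),
         USE.NAMES = FALSE)
}

#' Greedy identity-threshold clustering of a dereplicated pool
#'
#' Abundance-ordered centroid clustering (CD-HIT/USEARCH style): unique
#' sequences are visited in descending total count (ties broken by
#' lexicographic sequence order); each joins the first existing centroid, in
#' founding order, whose [pairwise_identity()] to it is at least
#' `identity_threshold` (the boundary is inclusive), otherwise it founds a
#' new cluster whose centroid is the founding sequence itself. Clustering is
#' performed jointly over all samples so that one cluster id tracks the same
#' sequence family across selection branches.
#'
#' @param uniques result of [dereplicate()].
#' @param identity_threshold fraction in `(0, 1]` (default 0.90).
#' @param min_report_copies clusters whose total is below this are dropped
#'   from the table (default 1 = keep all).
#' @return an object of class `cluster_table`: a list with `clusters`
#'   (data.frame: `cluster_id`, `representative`, `rep_exact_total`, `total`),
#'   `copies` (integer matrix cluster x sample) and `sample_totals` (the
#'   per-sample retained read counts; copies columns sum to these).
#' @export
cluster_pool <- function(uniques, identity_threshold = 0.90,
                         min_report_copies = 1L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  seqs <- uniques$sequence
  counts <- uniques$counts
  samples <- colnames(counts)
  sample_totals <- stats::setNames(as.integer(colSums(counts)), samples)
  if (length(seqs) == 0L) {
    out <- list(clusters = data.frame(cluster_id = character(),
                                      representative = character(),
                                      rep_exact_total = integer(),
                                      total = integer(),
                                      stringsAsFactors = FALSE),
                copies = matrix(0L, 0L, length(samples),
                                dimnames = list(NULL, samples)),
                sample_totals = sample_totals)
    class(out) <- "cluster_table"
    return(out)
  }
  tot <- as.integer(rowSums(counts))
  ord <- order(-tot, seqs, method = "radix")
  seqs <- seqs[ord]; counts <- counts[ord, , drop = FALSE]; tot <- tot[ord]
  assign <- cpp_greedy_cluster(seqs, identity_threshold)

  ncl <- max(assign)
  copies <- matrix(0L, ncl, length(samples), dimnames = list(NULL, samples))
  for (j in seq_along(samples))
    copies[, j] <- as.integer(rowsum(counts[, j], assign)[, 1L])
  # representative: member with highest total count, tie lexicographic;
  # members arrive in exactly that order, so the first member per cluster wins
  first <- match(seq_len(ncl), assign)
  representative <- seqs[first]
  rep_exact_total <- tot[first]
  total <- as.integer(rowSums(copies))

  cluster_id <- paste0("sq-", seq_hash(representative))
  dup <- duplicated(cluster_id)
  if (any(dup))
    cluster_id[dup] <- paste0(cluster_id[dup], "-", seq_len(sum(dup)) + 1L)

  keep <- total >= min_report_copies
  ord2 <- order(-total[keep], representative[keep], method = "radix")
  idx <- which(keep)[ord2]
  copies <- copies[idx, , drop = FALSE]
  rownames(copies) <- cluster_id[idx]
  out <- list(clusters = data.frame(cluster_id = cluster_id[idx],
                                    representative = representative[idx],
                                    rep_exact_total = rep_exact_total[idx],
                                    total = total[idx],
                                    stringsAsFactors = FALSE),
              copies = copies,
              sample_totals = sample_totals)
  class(out) <- "cluster_table"
  out
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("Cluster table: %d clusters x %d samples (%s retained reads)\n",
              nrow(x$clusters), length(x$sample_totals),
              format(sum(x$sample_totals), big.mark = ",")))
  if (nrow(x$clusters)) {
    top <- utils::head(x$clusters, 5L)
    cat("  top clusters (total copies):\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s  %s  %d\n", top$cluster_id[i],
                  top$representative[i], top$total[i]))
  }
  invisible(x)
}

#' Write a cluster table to TSV and its representatives to FASTA
#'
#' @param ct a `cluster_table`.
#' @param tsv path for the table (`cluster_id`, `representative`, one
#'   copy-number column per sample, `total`).
#' @param fasta optional path for representative sequences.
#' @return invisibly, `tsv`.
#' @export
write_clusters <- function(ct, tsv, fasta = NULL) {
  df <- cbind(ct$clusters[, c("cluster_id", "representative")],
              as.data.frame(ct$copies, stringsAsFactors = FALSE),
              total = ct$clusters$total)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(ct$clusters$representative)
    names(x) <- ct$clusters$cluster_id
    Biostrings::writeXStringSet(x, fasta)
  }
  invisible(tsv)
}
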