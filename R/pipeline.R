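#' Run the full analysis pipeline on raw read pairs
#'
#' Chains the stages: demultiplex, merge/extract variable regions,
#' dereplicate, cluster at the identity threshold, compute pool fractions
#' and assemble the enrichment table. Reads can be supplied as one
#' multiplexed set or as a list of chunks (e.g. lanes, or per-sample
#' emissions from the simulator); chunks are processed independently and
#' their records pooled, which keeps memory proportional to a chunk.
#'
#' @param chunks either `list(fwd=, rev=)` or a list of such chunk lists.
#' @param sheet a [sample_sheet()].
#' @param design a [library_design()].
#' @param identity_threshold clustering identity threshold (default 0.90).
#' @param max_mismatch barcode mismatch tolerance (default 0).
#' @param constant_mismatch constant-region mismatch tolerance (default 0).
#' @param min_overlap minimum read overlap for merging (default 10).
#' @param allow_unmerged single-read extraction fallback (default TRUE).
#' @param input_sample label of the unselected input sample.
#' @param min_report_copies cluster-table reporting floor (default 1).
#' @return list with `cluster_table`, `fractions`, `enrichment`, `report`
#'   (rejection report) and `retained` (per-sample retained read counts).
#' @export
run_pipeline <- function(chunks, sheet, design,
                         identity_threshold = 0.90,
                         max_mismatch = 0L, constant_mismatch = 0L,
                         min_overlap = 10L, allow_unmerged = TRUE,
                         input_sample = "input", min_report_copies = 1L) {
  if (!is.null(chunks$fwd)) chunks <- list(chunks)
  recs <- list(); reps <- list()
  retained <- stats::setNames(integer(nrow(sheet)), sheet$sample_id)
  for (ch in chunks) {
    pp <- preprocess_run(ch$fwd, ch$rev, sheet, design,
                         max_mismatch = max_mismatch,
                         constant_mismatch = constant_mismatch,
                         min_overlap = min_overlap,
                         allow_unmerged = allow_unmerged)
    recs[[length(recs) + 1L]] <- pp$records
    reps[[length(reps) + 1L]] <- pp$report
    retained <- retained + pp$retained
  }
  records <- do.call(rbind, recs)
  report <- do.call(rbind, reps)
  if (!is.null(report) && nrow(report)) {
    report <- stats::aggregate(count ~ sample_id + reason, report, sum)
  }
  empty <- names(retained)[retained == 0L]
  if (length(empty)) {
    warning("sample(s) with no retained reads dropped: ",
            paste(empty, collapse = ", "))
  }
  samples <- names(retained)[retained > 0L]
  uniq <- dereplicate(records, samples = samples)
  ct <- cluster_pool(uniq, identity_threshold = identity_threshold,
                     min_report_copies = min_report_copies)
  fr <- pool_fractions(ct)
  et <- enrichment_table(fr, sheet, ct, input_sample = input_sample)
  list(cluster_table = ct, fractions = fr, enrichment = et,
       report = report, retained = retained)
}

#' Read a cluster table written by [write_clusters()]
#'
#' @param tsv path to the table.
#' @return a `cluster_table`.
#' @export
read_clusters <- function(tsv) {
  df <- utils::read.table(tsv, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  samples <- setdiff(colnames(df), c("cluster_id", "representative", "total"))
  copies <- as.matrix(df[, samples, drop = FALSE])
  mode(copies) <- "integer"
  rownames(copies) <- df$cluster_id
  out <- list(clusters = data.frame(cluster_id = df$cluster_id,
                                    representative = df$representative,
                                    rep_exact_total = NA_integer_,
                                    total = as.integer(df$total),
                                    stringsAsFactors = FALSE),
              copies = copies,
              sample_totals = stats::setNames(as.integer(colSums(copies)),
                                              samples))
  class(out) <- "cluster_table"
  out
}
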