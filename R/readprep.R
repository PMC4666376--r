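#' Read a pair of FASTQ files
#'
#' Loads paired reads into memory as plain character vectors. Base qualities
#' are not used anywhere in the pipeline and are dropped on input. Files may
#' be plain or gzip-compressed.
#'
#' @param r1,r2 paths to the forward and reverse FASTQ file.
#' @return a list with elements `fwd`, `rev` (character vectors) and `id`
#'   (read identifiers from the R1 file).
#' @export
read_fastq_pair <- function(r1, r2) {
  f <- Biostrings::readDNAStringSet(r1, format = "fastq")
  r <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(f) != length(r))
    stop("R1 and R2 contain different numbers of reads")
  list(fwd = unname(as.character(f)), rev = unname(as.character(r)),
       id = sub(" .*", "", names(f)))
}

.REASONS <- c("merge_failed", "constant_mismatch",
              "length_out_of_range", "ambiguous_base")

#' Demultiplex barcoded read pairs
#'
#' Assigns each read pair to the sample whose forward/reverse barcodes match
#' the 5' ends of the two reads within `max_mismatch` substitutions. A pair
#' matching no entry, or more than one, is rejected with a reason code. The
#' two physical files may be in either orientation: a pair whose barcodes
#' match with the mates exchanged is assigned and reoriented, so results do
#' not depend on which file was passed as R1.
#'
#' @param fwd,rev character vectors of raw read sequences (barcodes still
#'   attached at the 5' end).
#' @param sheet a [sample_sheet()].
#' @param max_mismatch allowed substitutions per barcode (default 0, exact).
#' @param strip drop the barcode bases from the assigned reads (default TRUE).
#' @return a list with `samples` (named list, per sample a list with `fwd`
#'   and `rev` reads, reoriented and barcode-stripped), `assigned` (named
#'   integer counts) and `rejected` (counts by reason:
#'   `no_barcode_match`, `ambiguous_barcode`).
#' @export
demultiplex <- function(fwd, rev, sheet, max_mismatch = 0L, strip = TRUE) {
  stopifnot(inherits(sheet, "sample_sheet"), length(fwd) == length(rev),
            max_mismatch >= 0L)
  if (length(fwd) == 0L) {
    empty <- stats::setNames(
      rep(list(list(fwd = character(), rev = character())), nrow(sheet)),
      sheet$sample_id)
    return(list(samples = empty,
                assigned = stats::setNames(integer(nrow(sheet)), sheet$sample_id),
                rejected = c(no_barcode_match = 0L, ambiguous_barcode = 0L)))
  }
  hit <- cpp_demux(fwd, rev, sheet$barcode_fwd, sheet$barcode_rev,
                   as.integer(max_mismatch))
  idx <- hit$sample
  swapped <- hit$swapped
  samples <- vector("list", nrow(sheet))
  names(samples) <- sheet$sample_id
  for (k in seq_len(nrow(sheet))) {
    sel <- which(idx == k)
    sw <- swapped[sel]
    f <- ifelse(sw, rev[sel], fwd[sel])
    r <- ifelse(sw, fwd[sel], rev[sel])
    if (strip && length(sel)) {
      f <- substring(f, nchar(sheet$barcode_fwd[k]) + 1L)
      r <- substring(r, nchar(sheet$barcode_rev[k]) + 1L)
    }
    samples[[k]] <- list(fwd = f, rev = r)
  }
  assigned <- vapply(samples, function(s) length(s$fwd), integer(1))
  list(samples = samples,
       assigned = assigned,
       rejected = c(no_barcode_match = sum(idx == 0L),
                    ambiguous_barcode = sum(idx == -1L)))
}

#' Merge read pairs and extract the variable region
#'
#' Implements the inclusion filter applied to each demultiplexed pair: the
#' reverse read is reverse-complemented and merged with the forward read by
#' maximal exact suffix-prefix overlap (at least `min_overlap` nt, no
#' mismatches in the overlap); both constant regions must then be found in
#' the assembled amplicon within `constant_mismatch` substitutions; the
#' substring between them is kept iff its length lies inside the design's
#' variable-region window and it contains no ambiguous base. When the reads
#' do not overlap (long inserts), the region is still extracted if a single
#' read contains both constant-region anchors (`allow_unmerged`, default on).
#' Rejection is data, not an error: failed pairs return `NA` with a reason in
#' `merge_failed`, `constant_mismatch`, `length_out_of_range`,
#' `ambiguous_base`.
#'
#' @param fwd,rev character vectors of barcode-stripped read sequences.
#' @param design a [library_design()].
#' @param constant_mismatch allowed substitutions per constant region
#'   (default 0, exact).
#' @param min_overlap minimum exact read overlap for merging (default 10 nt).
#' @param allow_unmerged extract from a single read when both anchors are
#'   contained in it (default TRUE).
#' @return a list with `variable` (character, `NA` where rejected) and
#'   `reason` (factor with the rejection reasons, `NA` where accepted).
#' @export
pair_to_variable <- function(fwd, rev, design, constant_mismatch = 0L,
                             min_overlap = 10L, allow_unmerged = TRUE) {
  stopifnot(inherits(design, "library_design"), length(fwd) == length(rev))
  if (length(fwd) == 0L)
    return(list(variable = character(),
                reason = factor(character(), levels = .REASONS)))
  res <- cpp_extract_variable(fwd, rev,
                              design$fwd_constant, design$rev_constant,
                              design$var_len_min, design$var_len_max,
                              as.integer(constant_mismatch),
                              as.integer(min_overlap), allow_unmerged)
  reason <- factor(.REASONS[ifelse(res$reason == 0L, NA_integer_, res$reason)],
                   levels = .REASONS)
  list(variable = res$variable, reason = reason)
}

#' Run demultiplexing and variable-region extraction over a full run
#'
#' Convenience wrapper joining [demultiplex()] and [pair_to_variable()]:
#' turns one multiplexed read-pair set into per-sample variable-region
#' records plus a rejection report. For every sample,
#' `assigned = retained + rejected`, and pairs rejected at the barcode stage
#' are reported under sample `unassigned`.
#'
#' @inheritParams demultiplex
#' @inheritParams pair_to_variable
#' @return a list with `records` (data.frame: `sample_id`, `sequence`),
#'   `report` (data.frame: `sample_id`, `reason`, `count`) and `retained`
#'   (named integer counts per sample).
#' @export
preprocess_run <- function(fwd, rev, sheet, design,
                           max_mismatch = 0L, constant_mismatch = 0L,
                           min_overlap = 10L, allow_unmerged = TRUE) {
  dm <- demultiplex(fwd, rev, sheet, max_mismatch = max_mismatch)
  rec_list <- vector("list", nrow(sheet))
  rep_list <- list()
  for (k in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[k]
    s <- dm$samples[[k]]
    ex <- pair_to_variable(s$fwd, s$rev, design,
                           constant_mismatch = constant_mismatch,
                           min_overlap = min_overlap,
                           allow_unmerged = allow_unmerged)
    keep <- !is.na(ex$variable)
    rec_list[[k]] <- data.frame(sample_id = rep(sid, sum(keep)),
                                sequence = ex$variable[keep],
                                stringsAsFactors = FALSE)
    tab <- table(ex$reason[!keep])
    if (any(tab > 0))
      rep_list[[length(rep_list) + 1L]] <-
        data.frame(sample_id = sid, reason = names(tab),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  }
  for (rj in names(dm$rejected)) {
    if (dm$rejected[[rj]] > 0)
      rep_list[[length(rep_list) + 1L]] <-
        data.frame(sample_id = "unassigned", reason = rj,
                   count = as.integer(dm$rejected[[rj]]),
                   stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec_list)
  report <- if (length(rep_list)) do.call(rbind, rep_list) else
    data.frame(sample_id = character(), reason = character(),
               count = integer(), stringsAsFactors = FALSE)
  report <- report[report$count > 0, , drop = FALSE]
  list(records = records, report = report,
       retained = vapply(rec_list, nrow, integer(1)) |>
         stats::setNames(sheet$sample_id))
}

#' Write per-sample variable regions as FASTA
#'
#' One FASTA file per sample (record ids are running indices), the export
#' format consumed by the clustering step and by external tools.
#'
#' @param records data.frame with `sample_id` and `sequence` columns.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_variable_fasta <- function(records, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sid in unique(records$sample_id)) {
    seqs <- records$sequence[records$sample_id == sid]
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- seq_along(x)
    p <- file.path(outdir, paste0(sid, ".fasta"))
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
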