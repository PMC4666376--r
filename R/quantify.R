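#' Pool fraction of a sequence
#'
#' Copy number divided by the sample's total retained read count, expressed
#' in percent.
#'
#' @param copies copy number(s), `0 <= copies <= total`.
#' @param total total retained reads in the sample (> 0).
#' @return percentage(s) of pool.
#' @examples
#' pool_fraction(8975, 1580000) # ~0.57 % of the pool
#' @export
pool_fraction <- function(copies, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(copies < 0) || any(copies > total))
    stop("need 0 <= copies <= total")
  100 * copies / total
}

#' Pool-fraction table from a cluster table
#'
#' Divides every cluster's per-sample copy number by the sample's retained
#' read total. Each column sums to 100 (up to floating-point error).
#'
#' @param ct a `cluster_table` from [cluster_pool()].
#' @param pseudocount added to every copy number before normalising
#'   (default 0; exploratory use only, downstream scans already impose a
#'   copy-number floor).
#' @return an object of class `pool_fraction_table`: list with `values`
#'   (matrix cluster x sample, percent) and `sample_totals`.
#' @export
pool_fractions <- function(ct, pseudocount = 0) {
  stopifnot(inherits(ct, "cluster_table"), pseudocount >= 0)
  copies <- ct$copies + pseudocount
  totals <- colSums(copies)
  if (any(totals <= 0)) stop("sample with zero retained reads")
  values <- sweep(copies, 2L, totals, "/") * 100
  out <- list(values = values,
              sample_totals = ct$sample_totals)
  class(out) <- "pool_fraction_table"
  out
}

#' Enrichment factor
#'
#' Percentage of pool after selection divided by percentage of pool before
#' selection. Undefined (NA) when the sequence was absent before selection;
#' a sequence lost during selection has EF 0. No pseudo-counts are applied.
#'
#' @param pct_after,pct_before pool fractions in percent (vectorised).
#' @return non-negative EF values, `NA` where `pct_before` is 0.
#' @examples
#' enrichment_factor(0.655, 0.405) # 1.62
#' @export
enrichment_factor <- function(pct_after, pct_before) {
  if (any(pct_after < 0, na.rm = TRUE) || any(pct_before < 0, na.rm = TRUE))
    stop("pool fractions must be non-negative")
  ifelse(pct_before > 0, pct_after / pct_before, NA_real_)
}

#' Enrichment factor relative to wild type
#'
#' EF against a target variant divided by EF against wild type under the same
#' immobilisation mode. Undefined (NA) when the wild-type EF is 0 or itself
#' undefined.
#'
#' @param ef_variant,ef_wt enrichment factors (vectorised).
#' @return `ef_variant / ef_wt`, `NA` where not defined.
#' @export
relative_ef <- function(ef_variant, ef_wt) {
  ifelse(!is.na(ef_wt) & ef_wt > 0 & !is.na(ef_variant),
         ef_variant / ef_wt, NA_real_)
}

#' Assemble the enrichment table across selection branches
#'
#' For every cluster and every selected branch, computes the enrichment
#' factor versus the unselected input sample and, where the branch's
#' immobilisation mode has a wild-type reference branch, the EF relative to
#' wild type. Undefined values are flagged as `NA`, never dropped.
#'
#' @param fr a `pool_fraction_table` from [pool_fractions()].
#' @param sheet the [sample_sheet()] describing the samples.
#' @param ct the `cluster_table` the fractions came from (provides input
#'   copy numbers for downstream copy floors).
#' @param input_sample label of the unselected input sample.
#' @param wt_condition condition label of the wild-type reference branches.
#' @return an object of class `enrichment_table`: list with matrices `pct`
#'   (all samples), `ef` and `ef_rel_wt` (selected branches; NA = undefined),
#'   `input_copies`, `input_pct`, `input_sample` and the `sheet`.
#' @export
enrichment_table <- function(fr, sheet, ct, input_sample = "input",
                             wt_condition = "wt") {
  stopifnot(inherits(fr, "pool_fraction_table"), inherits(sheet, "sample_sheet"))
  samples <- colnames(fr$values)
  if (!input_sample %in% samples) stop("input sample not in fraction table")
  info <- sheet[match(samples, sheet$sample_id), , drop = FALSE]
  if (anyNA(info$sample_id)) stop("fraction table contains samples missing from the sheet")
  branches <- samples[samples != input_sample]
  binfo <- info[match(branches, info$sample_id), , drop = FALSE]

  special <- c("input", wt_condition, "latent", "complex")
  for (mode in unique(binfo$immobilisation)) {
    conds <- binfo$condition[binfo$immobilisation == mode]
    has_mutant <- any(!conds %in% special)
    has_wt <- any(conds == wt_condition)
    if (has_mutant && !has_wt)
      stop("immobilisation mode '", mode,
           "' has mutant branches but no wild-type reference")
  }

  pct <- fr$values
  before <- pct[, input_sample]
  ef <- matrix(NA_real_, nrow(pct), length(branches),
               dimnames = list(rownames(pct), branches))
  for (s in branches) ef[, s] <- enrichment_factor(pct[, s], before)
  rel <- matrix(NA_real_, nrow(pct), length(branches),
                dimnames = list(rownames(pct), branches))
  for (s in branches) {
    mode <- binfo$immobilisation[binfo$sample_id == s]
    wt_s <- binfo$sample_id[binfo$condition == wt_condition &
                            binfo$immobilisation == mode]
    if (length(wt_s) == 1L) rel[, s] <- relative_ef(ef[, s], ef[, wt_s])
  }
  input_copies <- if (!missing(ct)) {
    stats::setNames(ct$copies[, input_sample], rownames(ct$copies))
  } else {
    stats::setNames(rep(NA_integer_, nrow(pct)), rownames(pct))
  }
  out <- list(pct = pct, ef = ef, ef_rel_wt = rel,
              input_sample = input_sample,
              input_copies = input_copies,
              input_pct = stats::setNames(before, rownames(pct)),
              sheet = info)
  class(out) <- "enrichment_table"
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("Enrichment table: %d clusters x %d selected branches (input: %s)\n",
              nrow(x$ef), ncol(x$ef), x$input_sample))
  cat("  branches:", paste(colnames(x$ef), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten an enrichment table into long records
#'
#' @param x an `enrichment_table`.
#' @param ... unused.
#' @return data.frame with one row per (cluster, branch): pool fractions
#'   before/after, `ef`, `ef_rel_wt`, and explicit definedness flags.
#' @method as.data.frame enrichment_table
#' @export
as.data.frame.enrichment_table <- function(x, ...) {
  branches <- colnames(x$ef)
  info <- x$sheet[match(branches, x$sheet$sample_id), , drop = FALSE]
  cl <- rownames(x$ef)
  do.call(rbind, lapply(seq_along(branches), function(j) {
    data.frame(cluster_id = cl,
               branch_sample = branches[j],
               condition = info$condition[j],
               immobilisation = info$immobilisation[j],
               pct_before = unname(x$input_pct),
               pct_after = x$pct[, branches[j]],
               ef = x$ef[, j],
               ef_rel_wt = x$ef_rel_wt[, j],
               ef_defined = !is.na(x$ef[, j]),
               rel_defined = !is.na(x$ef_rel_wt[, j]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write pool fractions and enrichment records to TSV
#'
#' @param fr a `pool_fraction_table`.
#' @param et an `enrichment_table`.
#' @param pct_path,ef_path output paths.
#' @return invisibly, the paths written.
#' @export
write_enrichment <- function(fr, et, pct_path, ef_path) {
  pdf_ <- data.frame(cluster_id = rownames(fr$values),
                     as.data.frame(fr$values), check.names = FALSE)
  utils::write.table(pdf_, pct_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(et), ef_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pct_path, ef_path))
}

#' Replicate variability of pool fractions
#'
#' Per-sequence relative standard deviation (percent) of percentage-of-pool
#' values across replicate preparations of the same pool, with the summary
#' used to judge how large an enrichment-factor change is experimentally
#' meaningful.
#'
#' @param pct matrix of pool fractions, sequences x replicate preparations
#'   (at least two columns).
#' @return list with `per_sequence` (RSD in percent per sequence), `max` and
#'   `mean`.
#' @export
replicate_rsd <- function(pct) {
  pct <- as.matrix(pct)
  if (ncol(pct) < 2L) stop("need at least two replicate columns")
  m <- rowMeans(pct)
  if (any(m <= 0)) stop("sequences absent from all replicates")
  s <- apply(pct, 1L, stats::sd)
  rsd <- 100 * s / m
  list(per_sequence = rsd, max = max(rsd), mean = mean(rsd))
}
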