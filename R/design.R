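#' Library design: the anatomy of a valid amplicon
#'
#' Describes the fixed parts of the selection library: the constant regions
#' flanking the randomised insert and the admissible variable-region length
#' range. Sequences are stored in the DNA alphabet (T, not U) throughout the
#' package, since sequencing reads the cDNA; the reverse constant region is
#' given in the orientation of the amplicon top strand.
#'
#' @param fwd_constant 5' constant region (DNA, top strand).
#' @param rev_constant 3' constant region (DNA, top strand orientation).
#' @param var_len_min,var_len_max admissible variable-region length in nt.
#'   Pairs whose extracted insert falls outside this window are rejected.
#' @param read_length sequencing read length in nt.
#' @return an object of class `library_design`.
#' @examples
#' design <- default_library_design()
#' design
#' @export
library_design <- function(fwd_constant, rev_constant,
                           var_len_min = 25L, var_len_max = 45L,
                           read_length = 90L) {
  fwd_constant <- toupper(fwd_constant)
  rev_constant <- toupper(rev_constant)
  stopifnot(nzchar(fwd_constant), nzchar(rev_constant))
  .assert_dna(fwd_constant, "fwd_constant")
  .assert_dna(rev_constant, "rev_constant")
  var_len_min <- as.integer(var_len_min)
  var_len_max <- as.integer(var_len_max)
  if (var_len_min < 1L || var_len_min > var_len_max)
    stop("need 1 <= var_len_min <= var_len_max")
  structure(list(fwd_constant = fwd_constant, rev_constant = rev_constant,
                 var_len_min = var_len_min, var_len_max = var_len_max,
                 read_length = as.integer(read_length)),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("Library design\n")
  cat("  5' constant:", x$fwd_constant, sprintf("(%d nt)\n", nchar(x$fwd_constant)))
  cat("  3' constant:", x$rev_constant, sprintf("(%d nt)\n", nchar(x$rev_constant)))
  cat(sprintf("  variable region: %d-%d nt, read length %d nt\n",
              x$var_len_min, x$var_len_max, x$read_length))
  invisible(x)
}

#' Default 2'-F-Y RNA selection library design
#'
#' A realistic default: a 20-nt 5' constant region, a 38-nt 3' constant
#' region (the top-strand complement of a typical reverse selection primer),
#' and a 25-45 nt variable region read with 90-nt paired reads.
#'
#' @return a [library_design()].
#' @export
default_library_design <- function() {
  library_design(
    fwd_constant = "GGGAGACGACGTTAAGCAAC",
    rev_constant = "TTGATATAAATAGTGCCCATGGATCCGCGGGTGTCGGG",
    var_len_min = 25L, var_len_max = 45L, read_length = 90L)
}

# fixed 6-nt barcode set, pairwise Hamming distance >= 3
.BARCODES <- c(
  "TACAGT", "GGTAAT", "TATGCG", "CCTACG", "GAGTTG", "CAATCT", "TATCTA",
  "GCCAGC", "TTCGTT", "AAGGCA", "AGGTTC", "CCATAG", "AGCCAT", "GGCTTA",
  "ATGGAT", "GCGGCC", "GCTCAA", "CGAGTG", "TGGTGA", "CTTGCA", "AACAAG",
  "GGATGT", "TGAACT", "GGTCGC", "TTATCG", "TTCCAA", "TAAGAT", "AGTTGG",
  "CTGCGT", "AGCAGA", "TCCTCT", "TCGCCA", "GTACTC", "ATAACC", "CCAATC",
  "ACAGCG", "TGGCAC", "ACGATG", "GTCTGG", "CATAGC", "CCGAGA", "ACTTAT",
  "CACCGG", "TCTGAC", "TGCTAG", "GAACCA", "GGCGAC", "TAACGC")

#' Sample sheet: barcodes and selection-branch descriptors
#'
#' Maps dual barcodes to samples and records what each selection branch is:
#' the target condition (`input`, `wt`, a point mutant such as `R78A`, the
#' `latent` conformer, or the target-ligand `complex`), the immobilisation
#' mode (`poly_ab`, `mono_ab`, `vitronectin`, or `none` for the unselected
#' input pool) and the target conformation (`active`, `latent`, `na`).
#'
#' @param sample_id unique sample labels.
#' @param barcode_fwd,barcode_rev per-sample barcodes at the 5' end of the
#'   forward and reverse read; `(barcode_fwd, barcode_rev)` pairs must be
#'   unique.
#' @param condition branch condition label per sample.
#' @param immobilisation immobilisation mode per sample; the input branch
#'   must use `"none"`.
#' @param conformation target conformation per sample (default `"active"`,
#'   `"na"` for the input).
#' @return a `data.frame` of class `sample_sheet`.
#' @examples
#' default_sample_sheet()
#' @export
sample_sheet <- function(sample_id, barcode_fwd, barcode_rev, condition,
                         immobilisation,
                         conformation = ifelse(condition == "input", "na", "active")) {
  df <- data.frame(sample_id = as.character(sample_id),
                   barcode_fwd = toupper(barcode_fwd),
                   barcode_rev = toupper(barcode_rev),
                   condition = as.character(condition),
                   immobilisation = as.character(immobilisation),
                   conformation = as.character(conformation),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("sample_ids must be unique")
  if (anyDuplicated(paste(df$barcode_fwd, df$barcode_rev)))
    stop("duplicate (barcode_fwd, barcode_rev) pair in sample sheet")
  .assert_dna(df$barcode_fwd, "barcode_fwd")
  .assert_dna(df$barcode_rev, "barcode_rev")
  ok_mode <- c("poly_ab", "mono_ab", "vitronectin", "none")
  if (!all(df$immobilisation %in% ok_mode))
    stop("immobilisation must be one of: ", paste(ok_mode, collapse = ", "))
  bad <- df$condition == "input" & df$immobilisation != "none"
  if (any(bad)) stop("input samples must have immobilisation = 'none'")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Default branched-selection sample sheet
#'
#' The study layout this package targets: one unselected input sample; wild
#' type plus a seven-mutant alanine panel under two antibody immobilisation
#' modes; a latent-conformer branch; and a target:vitronectin complex branch.
#'
#' @param panel mutant condition labels for the alanine panel.
#' @return a [sample_sheet()].
#' @export
default_sample_sheet <- function(panel = c("K71A", "R78A", "Y81A", "K82A",
                                           "F116A", "R120A", "K124A")) {
  conds <- c("wt", panel)
  sample_id <- c("input",
                 paste0(conds, "_poly"),
                 paste0(conds, "_mono"),
                 "latent_mono", "complex_vn")
  condition <- c("input", conds, conds, "latent", "complex")
  immob <- c("none",
             rep("poly_ab", length(conds)),
             rep("mono_ab", length(conds)),
             "mono_ab", "vitronectin")
  conf <- c("na", rep("active", 2L * length(conds)), "latent", "active")
  n <- length(sample_id)
  if (n > length(.BARCODES)) stop("not enough built-in barcodes")
  sample_sheet(sample_id,
               barcode_fwd = .BARCODES[seq_len(n)],
               barcode_rev = rev(.BARCODES)[seq_len(n)],
               condition = condition, immobilisation = immob,
               conformation = conf)
}

#' Read or write a selection-experiment configuration
#'
#' The library design and sample sheet travel together as a single YAML
#' document, the hand-off format between the simulator, the CLI and the
#' pipeline.
#'
#' @param design a [library_design()].
#' @param sheet a [sample_sheet()].
#' @param path file to write to / read from.
#' @return `write_selex_config` returns `path` invisibly;
#'   `read_selex_config` returns `list(design, sheet)`.
#' @export
write_selex_config <- function(design, sheet, path) {
  stopifnot(inherits(design, "library_design"), inherits(sheet, "sample_sheet"))
  cfg <- list(
    library = unclass(design),
    samples = lapply(seq_len(nrow(sheet)), function(i) as.list(sheet[i, ])))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_selex_config
#' @export
read_selex_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- do.call(library_design, cfg$library)
  rows <- do.call(rbind, lapply(cfg$samples, function(s)
    as.data.frame(s, stringsAsFactors = FALSE)))
  sheet <- sample_sheet(rows$sample_id, rows$barcode_fwd, rows$barcode_rev,
                        rows$condition, rows$immobilisation, rows$conformation)
  list(design = design, sheet = sheet)
}
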