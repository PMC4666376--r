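#' Reverse-complement DNA sequences
#'
#' Vectorised reverse complement over the `A/C/G/T/N` alphabet (case kept,
#' unknown letters become `N`).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "GATTACA"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

#' Stable sequence-derived identifiers
#'
#' Hashes each sequence (32-bit FNV-1a) into an 8-hex-digit tag used to build
#' cluster ids that are stable across runs and independent of what else is in
#' the pool.
#'
#' @param x character vector of sequences.
#' @return character vector of 8-character hex tags.
#' @keywords internal
seq_hash <- function(x) cpp_seq_hash(x)

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Counter-based seed splitting: every randomised stage (one simulated
#' sample, one replicate) derives its own stream from the master seed and a
#' label, so stages are independently reproducible. Result stays below 2^31.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- strtoi(substr(cpp_seq_hash(as.character(label)), 1, 7), base = 16L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains letters outside the %s alphabet: %s",
                 what, if (allow_n) "A/C/G/T/N" else "A/C/G/T",
                 paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# IUPAC degenerate codes keyed by their sorted base set
.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- unname(.IUPAC[key])
  if (is.na(code)) stop("not a DNA base set: ", key)
  code
}

#' Expand an IUPAC degenerate string into the bases each position allows
#'
#' @param x a single IUPAC string.
#' @return list of character vectors, one per position.
#' @export
iupac_expand <- function(x) {
  rev_map <- stats::setNames(names(.IUPAC), unname(.IUPAC))
  lapply(strsplit(x, "")[[1]], function(ch) {
    key <- unname(rev_map[ch])
    if (is.na(key)) stop("unknown IUPAC letter: ", ch)
    strsplit(key, "")[[1]]
  })
}
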