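#' Motif-search parameters
#'
#' Settings for the greedy consensus-motif finder: ungapped motifs of width
#' `width_min` to `width_max`, at most one occurrence per sequence (ZOOPS),
#' given strand only, up to `max_motifs` motifs supported by `min_sites` to
#' `max_sites` member sequences, with consensus letters requiring
#' `conservation_min` per-position conservation.
#'
#' @param width_min,width_max motif width bounds in nt (defaults 5 and 40).
#' @param max_motifs maximum number of distinct motifs reported (default 25).
#' @param min_sites minimum number of member sequences supporting a motif
#'   (default 10).
#' @param max_sites cap on the number of sites per motif (default 300).
#' @param conservation_min per-position conservation for consensus letters
#'   (default 0.90).
#' @return an object of class `motif_params`.
#' @export
motif_params <- function(width_min = 5L, width_max = 40L, max_motifs = 25L,
                         min_sites = 10L, max_sites = 300L,
                         conservation_min = 0.90) {
  stopifnot(width_min >= 1, width_min <= width_max,
            conservation_min > 0, conservation_min <= 1,
            min_sites >= 1, max_sites >= min_sites, max_motifs >= 1)
  structure(list(width_min = as.integer(width_min),
                 width_max = as.integer(width_max),
                 max_motifs = as.integer(max_motifs),
                 min_sites = as.integer(min_sites),
                 max_sites = as.integer(max_sites),
                 conservation_min = conservation_min),
            class = "motif_params")
}

.BASES <- c("A", "C", "G", "T")

# column base frequencies over a set of site windows; chars: matrix sites x width
.col_freqs <- function(chars) {
  t(apply(chars, 2L, function(col) {
    tab <- table(factor(col, levels = .BASES))
    as.numeric(tab) / length(col)
  }))
}

#' IUPAC consensus from per-position base frequencies
#'
#' Each position becomes a single base when that base covers at least
#' `conservation_min` of the sites; otherwise the minimal IUPAC degenerate
#' code over the most frequent bases whose cumulative frequency reaches
#' `conservation_min` (ties broken alphabetically).
#'
#' @param freqs numeric matrix, width x 4, columns `A`, `C`, `G`, `T`; or a
#'   motif object from [find_motifs()].
#' @param conservation_min conservation level (default 0.90).
#' @return a single IUPAC string.
#' @examples
#' consensus_string(rbind(c(0.95, 0.05, 0, 0), c(0.55, 0, 0.40, 0.05))) # "AR"
#' @export
consensus_string <- function(freqs, conservation_min = 0.90) {
  if (inherits(freqs, "selex_motif")) freqs <- freqs$per_position_freqs
  freqs <- as.matrix(freqs)
  stopifnot(ncol(freqs) == 4L)
  colnames(freqs) <- .BASES
  letters <- apply(freqs, 1L, function(f) {
    ord <- order(-f, .BASES, method = "radix")
    if (f[ord[1L]] >= conservation_min - 1e-12) return(.BASES[ord[1L]])
    k <- which(cumsum(f[ord]) >= conservation_min - 1e-12)[1L]
    if (is.na(k)) k <- 4L
    iupac_code(.BASES[ord[seq_len(k)]])
  })
  paste(letters, collapse = "")
}

#' Discover conserved ungapped motifs within an aptamer family
#'
#' A deterministic greedy seed-and-extend finder playing the role an EM
#' motif tool (MEME-like, ZOOPS model) plays in this analysis: (1) all
#' `width_min`-mers over the unmasked sequence are scored by the number of
#' distinct member sequences containing them (ties broken lexicographically);
#' (2) the top seed's leftmost occurrence in each containing sequence is
#' taken as its site (zero or one per member); (3) the window is grown left
#' and right while every added column keeps a majority-base frequency of at
#' least `conservation_min` across sites (the side with the better-conserved
#' column is added first) up to `width_max`; (4) the motif's sites are masked
#' and the search repeats until `max_motifs` motifs or no seed reaches
#' `min_sites` support. Short, highly conserved motifs are recovered exactly;
#' no E-value statistics are computed.
#'
#' @param family character vector of member sequences (given strand).
#' @param params a [motif_params()].
#' @return list of `selex_motif` objects (possibly empty), each with
#'   `consensus` (IUPAC), `width`, `sites` (data.frame `seq`, `offset`,
#'   1-based), `per_position_freqs` and `n_sites`.
#' @export
find_motifs <- function(family, params = motif_params()) {
  family <- toupper(as.character(family))
  if (length(family) < params$min_sites) {
    warning("family smaller than min_sites (", length(family), " < ",
            params$min_sites, "); no motifs searched")
    return(list())
  }
  .assert_dna(family, "family sequences")
  chars <- strsplit(family, "")
  masked <- lapply(chars, function(x) rep(FALSE, length(x)))
  k <- params$width_min
  motifs <- list()

  for (iter in seq_len(params$max_motifs)) {
    # enumerate unmasked k-mer windows per sequence
    occs <- vector("list", length(family))
    for (i in seq_along(family)) {
      L <- length(chars[[i]])
      if (L < k) { occs[[i]] <- data.frame(kmer = character(), off = integer()); next }
      off <- seq_len(L - k + 1L)
      ok <- vapply(off, function(o) !any(masked[[i]][o:(o + k - 1L)]), logical(1))
      off <- off[ok]
      km <- vapply(off, function(o) paste(chars[[i]][o:(o + k - 1L)], collapse = ""),
                   character(1))
      occs[[i]] <- data.frame(kmer = km, off = off, stringsAsFactors = FALSE)
    }
    support <- table(unlist(lapply(occs, function(d) unique(d$kmer))))
    if (length(support) == 0L) break
    best_n <- max(support)
    if (best_n < params$min_sites) break
    seed <- sort(names(support)[support == best_n])[1L]

    # leftmost occurrence per containing sequence (zero-or-one), capped
    site_seq <- integer(); site_off <- integer()
    for (i in seq_along(family)) {
      hit <- occs[[i]]$off[occs[[i]]$kmer == seed]
      if (length(hit)) { site_seq <- c(site_seq, i); site_off <- c(site_off, min(hit)) }
    }
    if (length(site_seq) > params$max_sites) {
      site_seq <- site_seq[seq_len(params$max_sites)]
      site_off <- site_off[seq_len(params$max_sites)]
    }

    start <- site_off; end <- site_off + k - 1L
    col_cons <- function(pos_vec) {
      b <- vapply(seq_along(site_seq),
                  function(s) chars[[site_seq[s]]][pos_vec[s]], character(1))
      max(table(factor(b, levels = .BASES))) / length(b)
    }
    repeat {
      width <- end[1L] - start[1L] + 1L
      if (width >= params$width_max) break
      can_left <- all(start > 1L) &&
        !any(vapply(seq_along(site_seq),
                    function(s) masked[[site_seq[s]]][start[s] - 1L], logical(1)))
      can_right <- all(vapply(seq_along(site_seq),
                              function(s) end[s] < length(chars[[site_seq[s]]]) &&
                                !masked[[site_seq[s]]][end[s] + 1L], logical(1)))
      fl <- if (can_left) col_cons(start - 1L) else -1
      fr <- if (can_right) col_cons(end + 1L) else -1
      thr <- params$conservation_min - 1e-12
      if (fr >= thr && fr >= fl) end <- end + 1L
      else if (fl >= thr) start <- start - 1L
      else break
    }

    width <- end[1L] - start[1L] + 1L
    win <- t(vapply(seq_along(site_seq), function(s)
      chars[[site_seq[s]]][start[s]:end[s]], character(width)))
    freqs <- .col_freqs(win)
    colnames(freqs) <- .BASES
    motif <- structure(
      list(consensus = consensus_string(freqs, params$conservation_min),
           width = as.integer(width),
           sites = data.frame(seq = site_seq, offset = start),
           per_position_freqs = freqs,
           n_sites = length(site_seq)),
      class = "selex_motif")
    motifs[[length(motifs) + 1L]] <- motif
    for (s in seq_along(site_seq))
      masked[[site_seq[s]]][start[s]:end[s]] <- TRUE
  }
  motifs
}

#' @export
print.selex_motif <- function(x, ...) {
  cat(sprintf("Motif %s (width %d, %d sites)\n", x$consensus, x$width, x$n_sites))
  invisible(x)
}

#' Export family member sequences as FASTA
#'
#' Hand-off point for external motif/structure tools: writes the
#' representative sequence of each requested cluster with the cluster id as
#' FASTA header.
#'
#' @param cluster_ids clusters to export.
#' @param ct a `cluster_table`.
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
export_family_fasta <- function(cluster_ids, ct, path) {
  stopifnot(inherits(ct, "cluster_table"))
  idx <- match(cluster_ids, ct$clusters$cluster_id)
  if (anyNA(idx)) stop("unknown cluster id(s): ",
                       paste(cluster_ids[is.na(idx)], collapse = ", "))
  if (length(idx) == 0L) warning("no clusters to export; writing empty file")
  x <- Biostrings::DNAStringSet(ct$clusters$representative[idx])
  names(x) <- ct$clusters$cluster_id[idx]
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Letter-probability matrices in the MEME minimal text format, so
#' downstream tooling expecting MEME output can consume the finder's motifs
#' (or real MEME results can be substituted).
#'
#' @param motifs list of `selex_motif` objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_meme_minimal <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      m$width, m$n_sites), con)
    apply(m$per_position_freqs, 1L, function(f)
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", f[1], f[2], f[3], f[4]), con))
    writeLines("", con)
  }
  invisible(path)
}
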