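#' Default ground-truth family layout for simulated pools
#'
#' Five planted aptamer families spanning the binding-site patterns the
#' profiler is meant to recover: a four-residue core profile, the same core
#' plus one conformation-sensitive residue, and three alternative profiles
#' centred on the two hotspot residues. Each family carries one or two short
#' conserved motifs; one family is compatible with the target-ligand
#' complex, the others are competed by the ligand.
#'
#' @return data.frame with one row per family: `family_id`, `profile`
#'   (comma-joined mutants), `conformation`, `competition`, `motif1`,
#'   `motif2`.
#' @export
default_families <- function() {
  data.frame(
    family_id = paste0("fam", 1:5),
    profile = c("R78A,K82A,F116A,R120A",
                "R78A,K82A,F116A,R120A,K124A",
                "F116A,R120A",
                "R78A,F116A,R120A",
                "K82A,F116A,R120A"),
    conformation = c("binds_both", "active_preferring", "binds_both",
                     "binds_both", "binds_both"),
    competition = c("ligand_competed", "ligand_competed", "ligand_competed",
                    "ligand_competed", "complex_compatible"),
    motif1 = c("ACCACGTAG", "ACCGT", "GTCACGTAG", "GCCGTAG", "GCCGTAT"),
    motif2 = c("CGATC", "AGTTC", "CGATC", "TGATC", "CGATC"),
    stringsAsFactors = FALSE)
}

.rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(.BASES, len, replace = TRUE), collapse = ""), character(1))
}

# plant motifs into a random sequence at spread offsets; returns list with
# sequence and the positions occupied by motifs (1-based)
.plant_master <- function(len, motifs) {
  if (sum(nchar(motifs)) + length(motifs) > len)
    stop("planted motifs longer than the variable region")
  s <- sample(.BASES, len, replace = TRUE)
  protected <- logical(len)
  # deterministic, spread placement: first motif near the start, second
  # past the middle
  offs <- if (length(motifs) == 1L) 3L else
    c(3L, max(nchar(motifs[1L]) + 5L, floor(len / 2)) + 1L)
  for (i in seq_along(motifs)) {
    o <- offs[i]; w <- nchar(motifs[i])
    if (o + w - 1L > len) stop("planted motif does not fit the variable region")
    s[o:(o + w - 1L)] <- strsplit(motifs[i], "")[[1]]
    protected[o:(o + w - 1L)] <- TRUE
  }
  list(sequence = paste(s, collapse = ""), protected = protected,
       offsets = offs)
}

# mutate up to max_mut positions outside the protected motif positions
.mutate_member <- function(master_chars, protected, max_mut) {
  free <- which(!protected)
  n_mut <- sample.int(max_mut + 1L, 1L, prob = 0.5 ^ (0:max_mut)) - 1L
  if (n_mut > 0L) {
    pos <- sample(free, min(n_mut, length(free)))
    for (p in pos) {
      master_chars[p] <- sample(setdiff(.BASES, master_chars[p]), 1L)
    }
  }
  paste(master_chars, collapse = "")
}

#' Simulate a ground-truth selection pool
#'
#' Builds a fifth-round-like input pool: a handful of aptamer families (a
#' master sequence plus members mutated at up to `1 - identity_threshold` of
#' positions outside the planted motifs, so every member clusters with its
#' master) over a large background of unrelated sequences whose abundances
#' span from sub-percent level down to singleton scale. Background members
#' are survivors of earlier selection rounds: they bind the target uniformly
#' across the mutant panel (empty binding-site profile), and their
#' conformation/competition behaviour is drawn from realistic mixtures
#' (`p_background_active_preferring`, `p_background_competed`). Optionally a
#' tiny `rare` complex-compatible family far below the family detection
#' scale is planted.
#'
#' @param families data.frame as from [default_families()].
#' @param family_size members per family (default 20).
#' @param family_abundance total input frequency per family (default 0.6 %
#'   down to 0.1 %).
#' @param master_share fraction of a family's mass on its master (default 0.5).
#' @param n_background number of background sequences (default 1000).
#' @param background_range abundance span of the background, highest to
#'   lowest, before normalisation (default 5e-3 to 5e-6, log-spaced).
#' @param p_background_active_preferring,p_background_competed mixture
#'   probabilities for background truth labels.
#' @param rare_family plant the rare complex-compatible family (default FALSE).
#' @param rare_frequency total input frequency of the rare family (1e-5).
#' @param rare_size members in the rare family (default 3).
#' @param var_len variable-region length of family masters (default 40 nt).
#' @param design a [library_design()] (length bounds for background members).
#' @param identity_threshold clustering threshold the members must respect.
#' @param seed integer seed; the pool is deterministic given it.
#' @return an object of class `truth_pool`: list with `members` (data.frame:
#'   `sequence`, `frequency`, `family_id`, `is_master`, `profile`,
#'   `conformation`, `competition`), `families`, and the generating settings.
#' @export
truth_pool <- function(families = default_families(),
                       family_size = 20L,
                       family_abundance = c(0.006, 0.0045, 0.003, 0.002, 0.001),
                       master_share = 0.5,
                       n_background = 1000L,
                       background_range = c(5e-3, 5e-6),
                       p_background_active_preferring = 0.2,
                       p_background_competed = 0.7,
                       rare_family = FALSE,
                       rare_frequency = 1e-5,
                       rare_size = 3L,
                       var_len = 40L,
                       design = default_library_design(),
                       identity_threshold = 0.90,
                       seed = 1L) {
  stopifnot(nrow(families) == length(family_abundance),
            sum(family_abundance) < 1, master_share > 0, master_share <= 1)
  set.seed(derive_seed(seed, "truth_pool"))
  max_mut <- floor((1 - identity_threshold) * var_len)

  fam_list <- list()
  member_rows <- list()
  seen <- new.env(hash = TRUE)
  add_family <- function(fid, motifs, profile, conformation, competition,
                         total_freq, size) {
    planted <- .plant_master(var_len, motifs)
    master_chars <- strsplit(planted$sequence, "")[[1]]
    seqs <- planted$sequence
    tries <- 0L
    while (length(seqs) < size && tries < size * 50L) {
      cand <- .mutate_member(master_chars, planted$protected, max_mut)
      if (!cand %in% seqs) seqs <- c(seqs, cand)
      tries <- tries + 1L
    }
    w <- c(master_share, (1 - master_share) * 0.8 ^ (seq_len(length(seqs) - 1L)))
    w[-1] <- w[-1] / sum(w[-1]) * (1 - master_share)
    fam_list[[fid]] <<- list(master = planted$sequence, motifs = motifs,
                             motif_offsets = planted$offsets,
                             profile = profile, conformation = conformation,
                             competition = competition)
    member_rows[[length(member_rows) + 1L]] <<- data.frame(
      sequence = seqs,
      frequency = total_freq * w,
      family_id = fid,
      is_master = seq_along(seqs) == 1L,
      profile = paste(profile, collapse = ","),
      conformation = conformation,
      competition = competition,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(families))) {
    motifs <- c(families$motif1[i], families$motif2[i])
    motifs <- motifs[nzchar(motifs)]
    add_family(families$family_id[i], motifs,
               strsplit(families$profile[i], ",")[[1]],
               families$conformation[i], families$competition[i],
               family_abundance[i], family_size)
  }
  if (rare_family) {
    add_family("rare", c("GACTTCGGA"), character(),
               "binds_both", "complex_compatible",
               rare_frequency, rare_size)
  }

  bg_len <- sample(design$var_len_min:design$var_len_max, n_background,
                   replace = TRUE)
  bg_seq <- vapply(bg_len, function(L)
    paste(sample(.BASES, L, replace = TRUE), collapse = ""), character(1))
  planted_seqs <- unlist(lapply(member_rows, `[[`, "sequence"))
  dup <- duplicated(bg_seq) | bg_seq %in% planted_seqs
  while (any(dup)) {
    bg_seq[dup] <- vapply(bg_len[dup], function(L)
      paste(sample(.BASES, L, replace = TRUE), collapse = ""), character(1))
    dup <- duplicated(bg_seq) | bg_seq %in% planted_seqs
  }
  raw <- exp(seq(log(background_range[1]), log(background_range[2]),
                 length.out = n_background))
  fam_mass <- sum(vapply(member_rows, function(d) sum(d$frequency), numeric(1)))
  bg_freq <- raw / sum(raw) * (1 - fam_mass)
  bg_conf <- ifelse(runif(n_background) < p_background_active_preferring,
                    "active_preferring", "binds_both")
  bg_comp <- ifelse(runif(n_background) < p_background_competed,
                    "ligand_competed", "complex_compatible")
  member_rows[[length(member_rows) + 1L]] <- data.frame(
    sequence = bg_seq, frequency = bg_freq, family_id = "background",
    is_master = FALSE, profile = "", conformation = bg_conf,
    competition = bg_comp, stringsAsFactors = FALSE)

  members <- do.call(rbind, member_rows)
  members$frequency <- members$frequency / sum(members$frequency)
  out <- list(members = members, families = fam_list, design = design,
              identity_threshold = identity_threshold, var_len = var_len,
              seed = seed)
  class(out) <- "truth_pool"
  out
}

#' @export
print.truth_pool <- function(x, ...) {
  cat(sprintf("Truth pool: %d members (%d families + background)\n",
              nrow(x$members), length(x$families)))
  invisible(x)
}

#' Affinity model for a branched selection round
#'
#' Relative capture affinities per member and branch condition, plus a small
#' additive non-specific background retention. Binders' wild-type affinities
#' are log-normally spread and normalised to geometric mean 1. For each
#' mutant in a member's ground-truth profile, the affinity drops by a
#' per-member factor drawn from `fold_range` (at least twice the profiler's
#' two-fold call threshold by default); mutants outside the profile leave
#' affinity untouched. The latent branch reduces affinity for
#' active-preferring members; on the complex branch, ligand-competed members
#' lose specific binding entirely (the ligand occludes the shared site,
#' leaving background retention only) while the planted `rare` family's
#' affinity is multiplied by `rare_complex_boost`.
#'
#' @param pool a [truth_pool()].
#' @param panel mutant condition labels.
#' @param fold_range range of per-member affinity fold-drops (default 4-8).
#' @param background_retention additive non-specific retention (default 0.01).
#' @param wt_sdlog log-sd of binder wild-type affinities (default 0.5).
#' @param rare_complex_boost complex-branch affinity multiplier for the
#'   `rare` family (default 100).
#' @param seed integer seed.
#' @return an object of class `affinity_model`: list with `a` (matrix member
#'   x condition, conditions `wt`, panel, `latent`, `complex`) and
#'   `background_retention`.
#' @export
affinity_model <- function(pool,
                           panel = c("K71A", "R78A", "Y81A", "K82A",
                                     "F116A", "R120A", "K124A"),
                           fold_range = c(4, 8),
                           background_retention = 0.01,
                           wt_sdlog = 0.5,
                           rare_complex_boost = 100,
                           seed = 1L) {
  stopifnot(inherits(pool, "truth_pool"), fold_range[1] >= 1,
            background_retention >= 0)
  set.seed(derive_seed(seed, "affinity_model"))
  mem <- pool$members
  n <- nrow(mem)
  a_wt <- stats::rlnorm(n, 0, wt_sdlog)
  a_wt <- a_wt / exp(mean(log(a_wt)))   # geometric mean 1
  conds <- c("wt", panel, "latent", "complex")
  a <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
  a[, "wt"] <- a_wt
  prof <- strsplit(mem$profile, ",", fixed = TRUE)
  fold <- function() runif(n, fold_range[1], fold_range[2])
  for (m in panel) {
    hit <- vapply(prof, function(p) m %in% p, logical(1))
    a[, m] <- ifelse(hit, a_wt / fold(), a_wt)
  }
  a[, "latent"] <- ifelse(mem$conformation == "active_preferring",
                          a_wt / fold(), a_wt)
  # a ligand bound across the aptamer binding site occludes it completely:
  # competed members retain only the non-specific background on the complex
  a[, "complex"] <- ifelse(mem$competition == "ligand_competed", 0, a_wt)
  a[, "complex"] <- ifelse(mem$family_id == "rare",
                           a_wt * rare_complex_boost, a[, "complex"])
  structure(list(a = a, background_retention = background_retention,
                 panel = panel),
            class = "affinity_model")
}

# frequencies for one branch condition; "input"/"wt"/mutant/"latent"/"complex"
.branch_affinity <- function(model, condition) {
  if (condition == "input") return(NULL)
  if (!condition %in% colnames(model$a))
    stop("condition '", condition, "' not in affinity model")
  model$a[, condition]
}

#' One round of proportional-capture selection
#'
#' Post-selection frequencies under the linear capture model
#' `f'_i = f_i (a_i + b) / sum_j f_j (a_j + b)`, where `a` is the branch's
#' affinity column and `b` the non-specific background retention. The
#' unselected `input` condition returns the pool unchanged.
#'
#' @param pool a [truth_pool()].
#' @param model an [affinity_model()].
#' @param condition branch condition label.
#' @return numeric vector of post-selection frequencies (sums to 1).
#' @export
select_round <- function(pool, model, condition) {
  f <- pool$members$frequency
  a <- .branch_affinity(model, condition)
  if (is.null(a)) return(f)
  w <- f * (a + model$background_retention)
  tot <- sum(w)
  if (tot <= 0) stop("all capture affinities are zero for '", condition, "'")
  w / tot
}

#' Analytic expected enrichment factor
#'
#' The exact expectation (no sampling, no sequencing error) of a member's
#' enrichment factor on a branch:
#' `EF_i = (a_i + b) / sum_j f_j (a_j + b)`. Serves as the oracle against
#' which pipeline EF estimates are validated.
#'
#' @inheritParams select_round
#' @return numeric vector of expected EFs, one per pool member.
#' @export
expected_ef <- function(pool, model, condition) {
  f <- pool$members$frequency
  a <- .branch_affinity(model, condition)
  if (is.null(a)) return(rep(1, length(f)))
  ab <- a + model$background_retention
  ab / sum(f * ab)
}

#' Multinomial read sampling from pool frequencies
#'
#' @param freqs member frequencies (sum to 1).
#' @param n_reads reads to draw.
#' @param seed optional integer seed.
#' @return integer vector of per-member read counts.
#' @export
sample_pool_counts <- function(freqs, n_reads, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.integer(stats::rmultinom(1L, n_reads, freqs))
}

#' Simulated paired reads for one sample
#'
#' Wraps each drawn variable region with the constant flanks and the
#' sample's barcodes, splits the amplicon into an overlapping 90-nt read
#' pair (reverse read reverse-complemented) and applies i.i.d. substitution
#' errors.
#'
#' @param sequences member variable-region sequences.
#' @param counts per-member read counts (e.g. from [sample_pool_counts()]).
#' @param design a [library_design()].
#' @param barcode_fwd,barcode_rev the sample's barcodes.
#' @param error_rate per-base substitution probability (default 0.001).
#' @param min_overlap smallest read overlap the design must guarantee.
#' @param seed optional integer seed.
#' @return list with `fwd` and `rev` character vectors of reads.
#' @export
sim_reads <- function(sequences, counts, design, barcode_fwd, barcode_rev,
                      error_rate = 0.001, min_overlap = 10L, seed = NULL) {
  stopifnot(length(sequences) == length(counts), error_rate >= 0,
            error_rate < 0.1)
  if (!is.null(seed)) set.seed(seed)
  keep <- counts > 0L
  amplicon <- paste0(barcode_fwd, design$fwd_constant, sequences[keep],
                     design$rev_constant, revcomp(barcode_rev))
  too_long <- nchar(amplicon) > 2L * design$read_length - min_overlap
  if (any(too_long))
    stop("amplicon longer than 2*read_length - min_overlap; reads cannot overlap")
  amplicon <- rep(amplicon, counts[keep])
  fwd <- substr(amplicon, 1L, design$read_length)
  rev_ <- substr(revcomp(amplicon), 1L, design$read_length)
  if (error_rate > 0) {
    fwd <- cpp_add_errors(fwd, error_rate)
    rev_ <- cpp_add_errors(rev_, error_rate)
  }
  list(fwd = fwd, rev = rev_)
}

#' Write simulated reads as a FASTQ file pair
#'
#' @param reads list with `fwd` and `rev` (from [sim_reads()]).
#' @param r1,r2 output paths; a `.gz` suffix triggers gzip compression.
#' @param id_prefix read-name prefix.
#' @return invisibly, `c(r1, r2)`.
#' @export
write_fastq_pair <- function(reads, r1, r2, id_prefix = "sim") {
  write_one <- function(seqs, path, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    n <- length(seqs)
    qual <- vapply(nchar(seqs), function(L)
      paste(rep("I", L), collapse = ""), character(1))
    writeLines(paste0("@", id_prefix, ":", seq_len(n), "/", mate, "\n",
                      seqs, "\n+\n", qual), con)
  }
  write_one(reads$fwd, r1, 1L)
  write_one(reads$rev, r2, 2L)
  invisible(c(r1, r2))
}

#' Simulate a full branched-selection experiment
#'
#' For every sample in the sheet: applies one selection round under the
#' sample's branch condition (the input sample is left unselected), draws
#' `n_reads` members multinomially, and optionally synthesises barcoded,
#' error-bearing read pairs. Each sample draws from its own seed stream
#' derived from `seed`, so samples are independently reproducible.
#'
#' @param pool a [truth_pool()].
#' @param model an [affinity_model()].
#' @param sheet a [sample_sheet()].
#' @param n_reads reads per sample (default 2e5).
#' @param error_rate per-base substitution probability (default 0.001).
#' @param reads also synthesise read pairs (default FALSE: counts only).
#' @param seed master integer seed.
#' @return list with `counts` (matrix member x sample), `freqs` (expected
#'   post-selection frequencies per sample) and, if `reads`, `reads` (named
#'   list of `fwd`/`rev` read vectors per sample).
#' @export
sim_branched_experiment <- function(pool, model, sheet, n_reads = 2e5,
                                    error_rate = 0.001, reads = FALSE,
                                    seed = 1L) {
  stopifnot(inherits(pool, "truth_pool"), inherits(model, "affinity_model"),
            inherits(sheet, "sample_sheet"), n_reads >= 1)
  n <- nrow(pool$members)
  counts <- matrix(0L, n, nrow(sheet),
                   dimnames = list(NULL, sheet$sample_id))
  freqs <- matrix(0, n, nrow(sheet),
                  dimnames = list(NULL, sheet$sample_id))
  read_list <- if (reads) stats::setNames(vector("list", nrow(sheet)),
                                          sheet$sample_id) else NULL
  for (k in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[k]
    f <- select_round(pool, model, sheet$condition[k])
    freqs[, k] <- f
    counts[, k] <- sample_pool_counts(f, n_reads,
                                      seed = derive_seed(seed, paste0("counts:", sid)))
    if (reads) {
      read_list[[sid]] <- sim_reads(pool$members$sequence, counts[, k],
                                    pool$design, sheet$barcode_fwd[k],
                                    sheet$barcode_rev[k],
                                    error_rate = error_rate,
                                    seed = derive_seed(seed, paste0("reads:", sid)))
    }
  }
  list(counts = counts, freqs = freqs, reads = read_list)
}

#' Write the simulation ground truth as TSV
#'
#' @param pool a [truth_pool()].
#' @param model an [affinity_model()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(pool, model, path) {
  df <- cbind(pool$members,
              as.data.frame(model$a, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
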