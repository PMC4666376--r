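#' Parameters for binding-site profiling
#'
#' @param fold_threshold a residue is implicated when the EF relative to wild
#'   type drops *more* than this factor (default 2: `rel_ef < 0.5`, strict).
#' @param min_copies scan floor: clusters observed fewer times than this in
#'   the input pool are not profiled (default 10).
#' @param top_n number of most abundant input clusters entering the global
#'   hotspot summary (default 1000).
#' @param ef_wt_min hotspot summary considers clusters with wild-type EF
#'   above this (default 1).
#' @return an object of class `profiler_params`.
#' @export
profiler_params <- function(fold_threshold = 2, min_copies = 10L,
                            top_n = 1000L, ef_wt_min = 1) {
  stopifnot(fold_threshold > 1, min_copies >= 1)
  structure(list(fold_threshold = fold_threshold,
                 min_copies = as.integer(min_copies),
                 top_n = as.integer(top_n), ef_wt_min = ef_wt_min),
            class = "profiler_params")
}

#' Infer the binding-site profile of one cluster
#'
#' A mutant is included in the profile when the cluster's EF relative to wild
#' type for that mutant drops by strictly more than `fold_threshold`
#' (`rel_ef < 1/fold_threshold`; a value exactly at the boundary is
#' excluded). If any panel mutant's relative EF is undefined the profile is
#' flagged indeterminate rather than guessed.
#'
#' @param rel_efs named numeric vector of `EF_variant/EF_wt`, one entry per
#'   panel mutant (`NA` = undefined).
#' @param params a [profiler_params()].
#' @return character vector of implicated mutant labels, with attribute
#'   `indeterminate` (TRUE if any input was undefined).
#' @examples
#' infer_binding_profile(c(K71A = 1.0, R78A = 0.18, F116A = 0.17))
#' @export
infer_binding_profile <- function(rel_efs, params = profiler_params()) {
  if (is.null(names(rel_efs)) || any(!nzchar(names(rel_efs))))
    stop("rel_efs must be named by mutant")
  indet <- anyNA(rel_efs)
  residues <- if (indet) character() else
    names(rel_efs)[rel_efs < 1 / params$fold_threshold]
  structure(sort(residues), indeterminate = indet)
}

# relative-EF submatrix for one immobilisation mode, columns named by mutant
.mode_rel <- function(et, mode, panel) {
  info <- et$sheet
  sel <- info$sample_id[info$immobilisation == mode &
                        info$condition %in% panel]
  if (length(sel) < length(panel))
    stop("mode '", mode, "' lacks branches for: ",
         paste(setdiff(panel, info$condition[info$sample_id %in% sel]),
               collapse = ", "))
  m <- et$ef_rel_wt[, sel, drop = FALSE]
  colnames(m) <- info$condition[match(sel, info$sample_id)]
  m[, panel, drop = FALSE]
}

# default mutant panel: conditions that are not special labels
.default_panel <- function(et) {
  setdiff(unique(et$sheet$condition), c("input", "wt", "latent", "complex"))
}

#' Per-cluster binding profiles across immobilisation modes
#'
#' Infers the binding profile of every cluster above the input copy floor in
#' each requested immobilisation mode, and flags whether the modes agree
#' (concordant = identical residue sets, none indeterminate).
#'
#' @param et an `enrichment_table`.
#' @param params a [profiler_params()].
#' @param modes immobilisation modes that must each contain the full panel.
#' @param panel mutant condition labels (default: all non-special conditions
#'   in the table).
#' @return data.frame with `cluster_id`, `input_copies`, one comma-joined
#'   profile column per mode, per-mode indeterminate flags and `concordant`.
#' @export
profile_calls <- function(et, params = profiler_params(),
                          modes = c("poly_ab", "mono_ab"),
                          panel = .default_panel(et)) {
  stopifnot(inherits(et, "enrichment_table"))
  missing_modes <- setdiff(modes, unique(et$sheet$immobilisation))
  if (length(missing_modes))
    stop("requested mode(s) absent: ", paste(missing_modes, collapse = ", "))
  keep <- which(et$input_copies >= params$min_copies)
  keep <- keep[order(-et$input_copies[keep], names(et$input_copies)[keep],
                     method = "radix")]
  cl <- names(et$input_copies)[keep]
  if (length(cl) == 0L) {
    out <- data.frame(cluster_id = character(), input_copies = integer(),
                      stringsAsFactors = FALSE)
    for (m in modes) {
      out[[paste0("profile_", m)]] <- character()
      out[[paste0("indeterminate_", m)]] <- logical()
    }
    out$concordant <- logical()
    return(out)
  }
  rels <- lapply(modes, function(m) .mode_rel(et, m, panel)[cl, , drop = FALSE])
  names(rels) <- modes
  prof <- lapply(modes, function(m) {
    apply(rels[[m]], 1L, function(r)
      infer_binding_profile(r, params), simplify = FALSE)
  })
  names(prof) <- modes
  out <- data.frame(cluster_id = cl,
                    input_copies = unname(et$input_copies[cl]),
                    stringsAsFactors = FALSE)
  for (m in modes) {
    out[[paste0("profile_", m)]] <-
      vapply(prof[[m]], paste, character(1), collapse = ",")
    out[[paste0("indeterminate_", m)]] <-
      vapply(prof[[m]], function(p) attr(p, "indeterminate"), logical(1))
  }
  indet_any <- Reduce(`|`, lapply(modes, function(m) out[[paste0("indeterminate_", m)]]))
  same <- if (length(modes) == 1L) rep(TRUE, nrow(out)) else {
    ref <- out[[paste0("profile_", modes[1L])]]
    Reduce(`&`, lapply(modes[-1L], function(m) out[[paste0("profile_", m)]] == ref))
  }
  out$concordant <- same & !indet_any
  out
}

#' Scan the pool for clusters matching a reference binding profile
#'
#' Restricts to clusters observed at least `min_copies` times in the input
#' pool, infers each cluster's profile in every requested immobilisation
#' mode, and returns those whose profile equals the reference residue set
#' exactly (set equality; `superset = TRUE` relaxes this to "contains the
#' reference") in *all* modes. Indeterminate profiles never match.
#'
#' @param et an `enrichment_table`.
#' @param reference character vector of mutant labels (may be empty: matches
#'   clusters unaffected by every panel mutant).
#' @param params a [profiler_params()].
#' @param modes immobilisation modes whose profiles must agree with the
#'   reference.
#' @param panel mutant panel (default: all mutant conditions present).
#' @param superset accept profiles that contain the reference as a subset.
#' @return character vector of cluster ids, most abundant (input pool) first.
#' @export
scan_profile_matches <- function(et, reference, params = profiler_params(),
                                 modes = c("poly_ab", "mono_ab"),
                                 panel = .default_panel(et),
                                 superset = FALSE) {
  calls <- profile_calls(et, params, modes, panel)
  ref <- paste(sort(unique(reference)), collapse = ",")
  ok <- rep(TRUE, nrow(calls))
  for (m in modes) {
    p <- calls[[paste0("profile_", m)]]
    ok <- ok & !calls[[paste0("indeterminate_", m)]] &
      (if (superset) {
        vapply(strsplit(p, ","), function(x) all(reference %in% x), logical(1))
      } else p == ref)
  }
  calls$cluster_id[ok]
}

#' Conformational-preference call
#'
#' Compares a cluster's enrichment on the latent conformer against the
#' active form: a more than `fold_threshold`-fold drop means the aptamer
#' prefers active target; otherwise it binds both conformations. With no
#' enrichment on the active branch the call is indeterminate. The call is
#' invariant to scaling both EFs by a common factor.
#'
#' @param ef_active,ef_latent enrichment factors on the active and latent
#'   branches (vectorised).
#' @param params a [profiler_params()].
#' @return data.frame with `ratio` (`ef_latent/ef_active`) and `label` in
#'   `binds_both`, `active_preferring`, `indeterminate`.
#' @export
conformation_call <- function(ef_active, ef_latent, params = profiler_params()) {
  ratio <- ifelse(!is.na(ef_active) & ef_active > 0, ef_latent / ef_active,
                  NA_real_)
  label <- ifelse(is.na(ratio), "indeterminate",
                  ifelse(ratio < 1 / params$fold_threshold,
                         "active_preferring", "binds_both"))
  data.frame(ratio = ratio, label = label, stringsAsFactors = FALSE)
}

#' Ligand-competition call
#'
#' Compares enrichment on the target-ligand complex against the same target
#' displayed via an antibody: a more than `fold_threshold`-fold drop marks
#' the aptamer as competed by the ligand (overlapping binding site);
#' otherwise it is compatible with the complex.
#'
#' @param ef_antibody,ef_complex enrichment factors (vectorised).
#' @param params a [profiler_params()].
#' @return data.frame with `ratio` (`ef_complex/ef_antibody`) and `label` in
#'   `complex_compatible`, `ligand_competed`, `indeterminate`.
#' @export
competition_call <- function(ef_antibody, ef_complex, params = profiler_params()) {
  ratio <- ifelse(!is.na(ef_antibody) & ef_antibody > 0,
                  ef_complex / ef_antibody, NA_real_)
  label <- ifelse(is.na(ratio), "indeterminate",
                  ifelse(ratio < 1 / params$fold_threshold,
                         "ligand_competed", "complex_compatible"))
  data.frame(ratio = ratio, label = label, stringsAsFactors = FALSE)
}

#' Global binding-hotspot summary
#'
#' Over the `top_n` most abundant input-pool clusters, restricted to those
#' enriched on wild type (`EF_wt > ef_wt_min`): per mutant, the fraction of
#' clusters whose relative EF drops more than `fold_threshold`-fold; the
#' fraction unaffected by every mutant; and the per-mutant
#' `(EF_wt, EF_variant)` point clouds for plotting.
#'
#' @param et an `enrichment_table`.
#' @param params a [profiler_params()].
#' @param mode immobilisation mode analysed (default `poly_ab`).
#' @param panel mutant panel.
#' @return an object of class `hotspot_summary`: list with
#'   `fraction_reduced` (named per mutant), `fraction_none_reduced`,
#'   `n_top`, `n_high_ef`, and `points` (per mutant, data.frame of
#'   `ef_wt`/`ef_variant`).
#' @export
hotspot_summary <- function(et, params = profiler_params(), mode = "poly_ab",
                            panel = .default_panel(et)) {
  stopifnot(inherits(et, "enrichment_table"))
  info <- et$sheet
  wt_s <- info$sample_id[info$condition == "wt" & info$immobilisation == mode]
  if (length(wt_s) != 1L) stop("mode '", mode, "' needs exactly one wt branch")
  n_cl <- length(et$input_copies)
  top_n <- params$top_n
  if (n_cl < top_n) {
    warning("only ", n_cl, " clusters available; using all")
    top_n <- n_cl
  }
  ord <- order(-et$input_copies, names(et$input_copies), method = "radix")
  cl <- names(et$input_copies)[ord][seq_len(top_n)]
  ef_wt <- et$ef[cl, wt_s]
  rel <- .mode_rel(et, mode, panel)[cl, , drop = FALSE]
  mut_s <- info$sample_id[info$immobilisation == mode &
                          info$condition %in% panel]
  mut_cond <- info$condition[match(mut_s, info$sample_id)]
  high <- !is.na(ef_wt) & ef_wt > params$ef_wt_min
  thr <- 1 / params$fold_threshold
  reduced <- !is.na(rel[high, , drop = FALSE]) &
    rel[high, , drop = FALSE] < thr
  fraction_reduced <- colMeans(reduced)
  fraction_none <- mean(rowSums(reduced) == 0L)
  points <- lapply(stats::setNames(mut_s, mut_cond), function(s)
    data.frame(cluster_id = cl, ef_wt = ef_wt,
               ef_variant = et$ef[cl, s], row.names = NULL))
  structure(list(fraction_reduced = fraction_reduced,
                 fraction_none_reduced = fraction_none,
                 n_top = top_n, n_high_ef = sum(high),
                 mode = mode, points = points),
            class = "hotspot_summary")
}

#' @export
print.hotspot_summary <- function(x, ...) {
  cat(sprintf("Hotspot summary (%s): top %d clusters, %d with EF_wt above floor\n",
              x$mode, x$n_top, x$n_high_ef))
  cat("  fraction with >fold reduction per mutant:\n")
  for (m in names(x$fraction_reduced))
    cat(sprintf("    %-7s %.3f\n", m, x$fraction_reduced[m]))
  cat(sprintf("  fraction reduced for no mutant: %.3f\n", x$fraction_none_reduced))
  invisible(x)
}

#' Scatter plots of wild-type versus mutant enrichment factors
#'
#' One panel per mutant: each point is a cluster, x = EF on wild type,
#' y = EF on the mutant; the diagonal marks mutation-insensitive binding.
#'
#' @param x a `hotspot_summary`.
#' @param mutants subset of mutants to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @method plot hotspot_summary
#' @export
plot.hotspot_summary <- function(x, mutants = names(x$points), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(mutants)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in mutants) {
    p <- x$points[[m]]
    graphics::plot(p$ef_wt, p$ef_variant, pch = 20, cex = 0.5,
                   xlab = "EF wild type", ylab = paste("EF", m), main = m, ...)
    graphics::abline(0, 1, col = "grey50")
    graphics::abline(0, 0.5, col = "red3", lty = 2)
  }
  invisible(x)
}

#' Rank clusters by enrichment factor on one branch
#'
#' Orders clusters by EF on the given branch, highest first; clusters with
#' undefined EF rank last; ties are broken by input-pool abundance, then by
#' cluster id.
#'
#' @param et an `enrichment_table`.
#' @param branch sample id of the branch to rank by.
#' @return data.frame `cluster_id`, `ef`, `input_copies`, in rank order.
#' @export
rank_by_ef <- function(et, branch) {
  stopifnot(inherits(et, "enrichment_table"))
  if (!branch %in% colnames(et$ef)) stop("unknown branch: ", branch)
  ef <- et$ef[, branch]
  cl <- rownames(et$ef)
  key <- ifelse(is.na(ef), -Inf, ef)
  ord <- order(-key, -et$input_copies[cl], cl, method = "radix")
  data.frame(cluster_id = cl[ord], ef = ef[ord],
             input_copies = unname(et$input_copies[cl][ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}
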