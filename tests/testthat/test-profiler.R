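panel7 <- c("K71A", "R78A", "Y81A", "K82A", "F116A", "R120A", "K124A")

test_that("binding profiles collect mutants with >2-fold reduced relative EF", {
  rel <- c(K71A = 1.0, R78A = 0.18, Y81A = 0.9, K82A = 0.19,
           F116A = 0.17, R120A = 0.20, K124A = 0.7)
  p <- infer_binding_profile(rel)
  expect_equal(as.character(p), sort(c("R78A", "K82A", "F116A", "R120A")))
  expect_false(attr(p, "indeterminate"))

  none <- infer_binding_profile(stats::setNames(rep(1, 7), panel7))
  expect_length(none, 0L)

  # the boundary is strict: exactly 0.5 is NOT a call
  edge <- infer_binding_profile(c(R78A = 0.5, K82A = 0.4999))
  expect_equal(as.character(edge), "K82A")

  ind <- infer_binding_profile(c(R78A = NA, K82A = 0.1))
  expect_true(attr(ind, "indeterminate"))
  expect_length(ind, 0L)
})

test_that("profile inference is monotone in the relative EFs", {
  set.seed(41)
  for (i in 1:25) {
    rel <- stats::setNames(runif(7, 0, 2), panel7)
    base <- infer_binding_profile(rel)
    j <- sample(7, 1)
    rel2 <- rel
    rel2[j] <- rel2[j] * runif(1)
    expect_true(all(as.character(base) %in%
                    as.character(infer_binding_profile(rel2))))
  }
})

test_that("conformation calls follow the latent/active EF ratio", {
  expect_equal(conformation_call(1.5, 1.4)$label, "binds_both")
  expect_equal(conformation_call(1.5, 0.1)$label, "active_preferring")
  expect_equal(conformation_call(0, 0)$label, "indeterminate")
  # invariant under common scaling
  expect_equal(conformation_call(0.3, 0.04)$label,
               conformation_call(30, 4)$label)
})

test_that("competition calls follow the complex/antibody EF ratio", {
  expect_equal(competition_call(2, 0.2)$label, "ligand_competed")
  expect_equal(competition_call(2, 2)$label, "complex_compatible")
  expect_equal(competition_call(0, 5)$label, "indeterminate")
  expect_equal(competition_call(0.2, 0.08)$label,
               competition_call(20, 8)$label)
})

test_that("EF ranking is descending with undefined EFs last", {
  copies <- matrix(c(22L, 14850L,        # rare, hugely enriched
                     100L, 47000L,
                     10000L, 10000L,
                     0L, 500L,           # undefined EF
                     989878L, 927650L),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(c("hi", "mid", "one", "undef", "bg"),
                                   c("input", "complex_vn")))
  sheet <- sample_sheet(c("input", "complex_vn"), c("AAAAAA", "CCCCCC"),
                        c("TTTTTT", "GGGGGG"), c("input", "complex"),
                        c("none", "vitronectin"))
  ct <- make_ct(copies)
  et <- enrichment_table(pool_fractions(ct), sheet, ct)
  rk <- rank_by_ef(et, "complex_vn")
  expect_equal(rk$cluster_id, c("hi", "mid", "one", "bg", "undef"))
  expect_true(all(diff(rk$ef[1:4]) <= 0))
  expect_true(is.na(rk$ef[5]))
})

test_that("ties in EF rank by input abundance", {
  copies <- matrix(c(100L, 100L, 500L, 500L, 9400L, 9400L), 3, 2,
                   byrow = TRUE,
                   dimnames = list(c("small", "big", "bg"),
                                   c("input", "wt_poly")))
  sheet <- sample_sheet(c("input", "wt_poly"), c("AAAAAA", "CCCCCC"),
                        c("TTTTTT", "GGGGGG"), c("input", "wt"),
                        c("none", "poly_ab"))
  ct <- make_ct(copies)
  et <- enrichment_table(pool_fractions(ct), sheet, ct)
  rk <- rank_by_ef(et, "wt_poly")
  expect_equal(rk$cluster_id, c("bg", "big", "small"))
})

test_that("profile scan recovers planted families from counts-level data", {
  sheet <- default_sample_sheet()
  pool <- truth_pool(seed = 42)
  model <- affinity_model(pool, seed = 42)
  d <- counts_level_dataset(pool, model, sheet, n_reads = 1e5, seed = 42)
  fam_cl <- family_cluster_ids(pool, d$ct)
  truth <- family_truth_profiles(pool)
  for (f in names(fam_cl)) {
    hits <- scan_profile_matches(d$et, strsplit(truth[[f]], ",")[[1]])
    same_prof <- names(truth)[truth == truth[[f]]]
    expect_setequal(hits, unname(fam_cl[same_prof]))
  }
  # empty reference returns mutant-insensitive clusters only
  neutral <- scan_profile_matches(d$et, character())
  expect_false(any(fam_cl %in% neutral))
  expect_gt(length(neutral), 0L)
  # a copy floor above every cluster empties the scan
  high_floor <- profiler_params(min_copies = 10^7)
  expect_length(scan_profile_matches(d$et, strsplit(truth[[1]], ",")[[1]],
                                     high_floor), 0L)
  # scan is invariant to the order of the dereplicated input
  perm <- sample(length(pool$members$sequence))
  uniq_perm <- list(sequence = pool$members$sequence[perm],
                    counts = d$sim$counts[perm, , drop = FALSE])
  ct2 <- cluster_pool(uniq_perm)
  et2 <- enrichment_table(pool_fractions(ct2), sheet, ct2)
  expect_identical(scan_profile_matches(et2, strsplit(truth[[1]], ",")[[1]]),
                   scan_profile_matches(d$et, strsplit(truth[[1]], ",")[[1]]))
})

test_that("hotspot summary fractions are {0,1} when only one cluster is used", {
  copies <- rbind(only = c(60000L, 70000L, 10000L, 70000L, 70000L, 10000L),
                  bg = c(40000L, 30000L, 90000L, 30000L, 30000L, 90000L))
  colnames(copies) <- c("input", "wt_poly", "F116A_poly", "K71A_poly",
                        "wt_mono", "F116A_mono")
  sheet <- sample_sheet(colnames(copies),
                        branchedselex:::.BARCODES[1:6],
                        rev(branchedselex:::.BARCODES[7:12]),
                        c("input", "wt", "F116A", "K71A", "wt", "F116A"),
                        c("none", rep("poly_ab", 3), rep("mono_ab", 2)))
  ct <- make_ct(copies)
  et <- enrichment_table(pool_fractions(ct), sheet, ct)
  hs <- suppressWarnings(
    hotspot_summary(et, profiler_params(top_n = 1), mode = "poly_ab",
                    panel = c("F116A", "K71A")))
  expect_true(all(hs$fraction_reduced %in% c(0, 1)))
  expect_equal(unname(hs$fraction_reduced["F116A"]), 1)  # 0.1/2 < 0.5
  expect_equal(unname(hs$fraction_reduced["K71A"]), 0)   # 9/2 > 0.5
  expect_warning(hotspot_summary(et, profiler_params(top_n = 10),
                                 mode = "poly_ab",
                                 panel = c("F116A", "K71A")),
                 "using all")
})

test_that("a neutral mutant leaves hotspot EF points on the diagonal", {
  sheet <- default_sample_sheet()
  pool <- truth_pool(seed = 43)
  model <- affinity_model(pool, seed = 43)
  d <- counts_level_dataset(pool, model, sheet, n_reads = 2e5, seed = 43)
  hs <- suppressWarnings(hotspot_summary(d$et, profiler_params(top_n = 500)))
  expect_lt(unname(hs$fraction_reduced["K71A"]), 0.02)
  # every family's truth contains F116A/R120A: among enriched clusters those
  # fractions dominate the panel
  expect_gt(unname(hs$fraction_reduced["F116A"]), 0)
  pts <- hs$points$K71A
  ok <- !is.na(pts$ef_variant) & !is.na(pts$ef_wt) & pts$ef_wt > 0.5
  ratio <- pts$ef_variant[ok] / pts$ef_wt[ok]
  expect_lt(abs(stats::median(ratio) - 1), 0.1)
})
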