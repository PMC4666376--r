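---
title: "Branched-SELEX sequencing analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branched-SELEX sequencing analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchedselex)
```

## The measurement model

A branched-SELEX experiment takes one late-round aptamer pool and performs a
single further round of affinity selection in parallel against a panel of
target variants: wild-type protein, single-residue alanine mutants, an
alternative (latent) conformer, and the target in complex with a natural
ligand. Each branch, together with the unselected input pool, is barcoded and
sequenced. The analysis rests on one statistic, the enrichment factor

$$\mathrm{EF}_X(i) \;=\; \frac{p_{i,X}}{p_{i,\mathrm{input}}},$$

where $p$ denotes a sequence's *pool fraction* (copy number over retained
reads, in percent). Under a proportional-capture selection model — capture
probability linear in affinity, no saturation — the expectation is

$$\mathrm{EF}_X(i) \;=\; \frac{a_{i,X} + b}{\sum_j f_j\,(a_{j,X} + b)},$$

with $a_{i,X}$ the relative affinity of sequence $i$ for target variant $X$,
$b$ a small non-specific background retention, and $f_j$ the input pool
frequencies. Two consequences shape the entire package:

* EFs are *relative* within a branch: the denominator renormalises over the
  whole pool, so absolute EFs depend on pool composition, but ratios of EFs
  of the same sequence across branches cancel the wild-type affinity and the
  input-sampling noise. The binding-site signal therefore lives in
  $\mathrm{EF}_{\text{variant}}/\mathrm{EF}_{\text{wt}}$ (computed within one
  immobilisation mode).
* A sequence whose affinity for a mutant drops by a factor $\phi$ shows a
  relative EF of roughly $1/\phi$ (denominator shifts are second order when
  affected families are a small mass fraction). The two-fold call threshold
  thus corresponds to a two-fold affinity loss.

A mutated residue is *implicated in the binding site* when the relative EF
drops strictly more than two-fold (`rel_ef < 0.5`); the same fold rule,
applied to the latent-vs-active EF ratio, classifies conformational
preference, and applied to the complex-vs-antibody ratio, ligand
competition.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `identity_threshold` | 0.90 | clustering identity; groups a master sequence with its mutational/error halo |
| `fold_threshold` | 2 | strict call threshold on relative EF (boundary excluded) |
| `min_copies` | 10 | input-pool copy floor for profiling/scans; below it relative EFs are sampling noise |
| `top_n` | 1000 | clusters entering the hotspot summary |
| `ef_wt_min` | 1 | hotspot summary considers clusters actually enriched on wild type |
| `var_len_min/max` | 25/45 nt | inclusion window for extracted variable regions |
| `min_overlap` | 10 nt | minimum exact read overlap for pair merging |
| `background_retention` | 0.01 | non-specific capture affinity $b$ |
| `error_rate` | 0.001/base | substitution-only sequencing error in the simulator |
| `n_reads` | 2×10⁵ | simulated reads per sample (see problem sizes) |

The call threshold must be read against experimental variability: replicate
pool preparations differ by a few percent relative standard deviation per
sequence, far below a two-fold change, which is what makes the strict
`rel_ef < 0.5` rule meaningful.

## Read preparation

Reads are stored in the DNA alphabet (sequencing reads the cDNA); the
reverse constant region is kept in top-strand orientation. Demultiplexing
matches both barcodes at the 5′ ends of the mates, in either mate order, so
results do not depend on which physical file is "R1"; pairs matching zero
or several samples are rejected with reason codes, and
`assigned + rejected = total` always holds. Barcode and constant-region
matching default to exact (0 mismatches) — the inclusion rule is "correct
constant regions" — with tolerances exposed as arguments.

Pair merging uses the maximal exact suffix–prefix overlap of at least
`min_overlap` nt. No merge algorithm is prescribed by the assay itself; the
exact-overlap rule is the simplest deterministic choice, and a read pair
whose overlap contains a sequencing error is simply rejected (`merge_failed`)
rather than corrected — rejection is data, not failure, and affects all
members of a length class equally, so EF ratios are unaffected in
expectation. When the amplicon is too long for the mates to overlap, the
variable region is still extracted if a single mate contains both
constant-region anchors (on by default). Variable regions containing `N` are
rejected; base qualities are read but not used.

## Clustering

The identity of two sequences is defined constructively: the global
alignment maximising the number of matching columns (match +1, mismatch 0,
linear gap 0), taking among co-optimal alignments the one with the fewest
columns; identity = matches / columns. This makes identity 1.0 for equal
strings, 39/40 for one substitution *or* one indel in a 40-mer, and exactly
0.9 computable — the threshold boundary is inclusive (a pair at exactly 0.90
joins). Numerically the comparison uses a 10⁻⁹ tolerance so that ratios
representable only approximately in floating point (36/40 against a 0.9
threshold) behave as their exact rational values.

Clustering is greedy, abundance-ordered centroid clustering: unique
sequences are visited in descending total count with lexicographic
tie-break; each joins the first centroid (founding order) within the
threshold, else founds a cluster. Identity is computed against the centroid
only, and clustering is performed jointly over all samples so a single
cluster id tracks a family across branches — a requirement for EF
computation. Every ordering and tie rule is fixed, so identical input yields
byte-identical tables. Two exact-safe prescreens (a length-ratio bound and a
q-gram count lower bound derived from the maximal edit budget at the
threshold) skip hopeless centroid comparisons without ever skipping a
qualifying one; equivalence with a brute-force all-pairs oracle is asserted
in the test suite. The copy-number table reports cluster totals and retains
the representative's exact-sequence count separately, since "copies of a
sequence" can reasonably mean either.

"Dereplicate-then-cluster" is the assumed processing order; per-sample
totals are totals of *retained* (post-filter) reads, which is the table the
fractions are computed from.

## Quantification

Pool fractions per sample sum to 100 by construction. An EF with zero
pre-selection fraction is *undefined* and flagged, never imputed: a
pseudo-count would manufacture spurious EFs exactly where sampling noise is
worst, and the ≥10-copy scan floor already removes that stratum from
profiling. A zero post-selection fraction is a true EF of 0. Undefinedness
propagates: a cluster with any undefined panel relative EF yields an
*indeterminate* profile rather than a guessed one.

## Profiling

Profiles are sets of implicated mutants under the strict two-fold rule.
Scans for clusters matching a reference profile use exact set equality (a
`superset` relaxation exists but is off by default) and by default require
the same profile in both antibody immobilisation modes — concordance across
modes is the assay's own internal replication. Conformation calls label
`active_preferring` when the latent/active EF ratio falls below
`1/fold_threshold` and `binds_both` otherwise (a ratio *above* the threshold
still means the aptamer binds latent at least as well as active, hence
`binds_both`); with zero active-branch EF the call is `indeterminate`.
Competition calls mirror this for the complex/antibody ratio. Both calls are
invariant under common scaling of the two EFs, as any function of their
ratio must be. EF rankings place undefined EFs last and break ties by input
abundance, then cluster id.

## Motif discovery

The finder plays the role an EM motif tool (ZOOPS model) plays in this kind
of analysis, for the regime that matters here: short, highly conserved,
ungapped motifs in families of near-identical sequences. It is a greedy
seed-and-extend: score all `width_min`-mers by the number of distinct
members containing them; take the best seed (ties lexicographic), one
leftmost occurrence per member (zero-or-one); grow the window while every
added column keeps majority-base conservation ≥ 0.90, preferring the
better-conserved side (ties extend right); emit, mask the sites, repeat.
Consensus letters are the single base when it covers ≥ 90 % of sites, else
the minimal IUPAC code over the most frequent bases reaching 90 %
cumulative. The finder is fully deterministic, computes no E-values, and
writes MEME-minimal format so real MEME results can be substituted
downstream. Masking prevents rediscovery of overlapping variants of an
already-emitted motif.

## The simulator: what it emulates, and what it does not

`truth_pool()` builds a fifth-round-like input pool: five planted aptamer
families (master plus members mutated at up to 10 % of positions outside the
planted motifs, so families cluster with their masters by construction) over
1000 background sequences whose abundances are log-spaced from sub-percent
to singleton scale — mirroring a pool whose top sequence holds about half a
percent and whose tail runs into singletons. Default family profiles span
the patterns such screens report: a four-residue core site, the same core
plus a conformation-sensitive residue, and three alternatives centred on the
two hotspot residues; one family is complex-compatible, the others
ligand-competed; one mutant of the panel (K71A) is neutral everywhere and
serves as the negative control.

The affinity model draws binder wild-type affinities log-normally
(`sdlog = 0.5`, roughly an order-of-magnitude spread, normalised to
geometric mean 1 — EF spreads of near one order of magnitude among related
binders are realistic) and applies per-member fold-drops of 4–8 for profile
mutants: at least twice the call threshold, matching the 5–10-fold
reductions typical for residues genuinely in a binding site. On the complex
branch, competed members lose specific binding entirely (the ligand occludes
the shared site), leaving only background retention; this reproduces the
wide EF dynamic range (hundreds-fold) observed on complex branches.
Immobilisation modes are replicate branches with identical affinities and
independent sampling noise, since true binders profile identically across
modes. Selection is one round of the proportional-capture model; reads are
drawn multinomially and wrapped with constant regions and barcodes; errors
are i.i.d. substitutions.

Deliberately *not* modelled: PCR amplification bias and preparation
variability (so simulated replicate RSDs reflect resampling noise only and
sit below experimentally observed replicate spreads), indel sequencing
errors (the 25–45 nt length filter would absorb them), capture saturation
and inter-sequence competition beyond renormalisation, and chimera
formation. Passing tests therefore demonstrate correctness of the analysis
under sampling noise and substitution errors, not robustness to
amplification artefacts.

All randomness flows from one master seed through labelled seed streams
(`derive_seed`), making every sample independently reproducible and keeping
derived seeds below 2³¹.

## Problem sizes

The validation suite scales the experiment down to desk size, as its own
choice of problem size: 2×10⁵ reads per sample for read-level end-to-end
runs (19 samples), which leaves family clusters hundreds of copies deep —
ample for the two-fold rule with fold-drops ≥ 4. Two checks are count-level
only (no read synthesis) and therefore run at full study depth: replicate
RSD of pool preparations at 1.58×10⁶ reads, and the rare-binder ranking at
2×10⁶ reads, where a family planted at 10⁻⁵ frequency expects ~20 input
copies; at the scaled-down depth the same family would expect ~2 copies and
the check would measure Poisson zero-draws instead of ranking behaviour. EF
calibration uses 20 independent seeds and accepts estimates within 3
delta-method binomial standard errors of the analytic oracle for members at
frequency ≥ 10⁻⁴.

## Known limitations

* Identity is computed by exact dynamic programming; the clusterer is meant
  for up to ~10⁵ uniques per run, not for >10⁶-unique metagenome-scale
  inputs (no heuristic k-mer pre-clustering is attempted).
* EFs carry no confidence intervals; the copy floor and fold threshold are
  the only noise guards, and calls near the floor should be read
  accordingly.
* Round-to-round enrichment across multiple selection rounds is out of
  scope; the package models exactly one branched round against one input.
* The motif finder does not model gapped motifs, reverse strands or motif
  statistics; it recovers highly conserved short motifs and exports families
  for external structure/motif tools (secondary-structure prediction and
  alignment are explicitly out of scope).
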