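---
title: "Methods: species richness estimation from plant DNA barcodes"
author: "barcodeSurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species richness estimation from plant DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeSurvey)
```

## The problem

A floristic survey of a forest plot asks "how many species are here?".
Where the flora is taxonomically poorly known, or the material is sterile
or cryptic (seedlings, roots), answering by morphology requires scarce
expertise.  `barcodeSurvey` implements a DNA-barcode alternative: sample
every stem, sequence one or more chloroplast barcode loci (typically
*rbcLa*, *matK* and the *trnH-psbA* spacer), and count the species-level
groups the sequences support.  The package distinguishes two statistics
that behave very differently:

* **species discrimination accuracy** — the fraction of species whose
  samples are correctly recovered as exactly one group; and
* **species richness estimation accuracy** — how close the *count* of
  groups (after correcting for known contaminant sequences) comes to the
  true number of species in the plot.

Two sister species that fuse into one group ruin discrimination for both
of them but cost the richness count only one unit, so richness estimation
is systematically the easier task.  In a four-species plot where exactly
one such fusion occurs, discrimination is 2/4 = 50% while estimation is
3/4 = 75%; both numbers are recomputed end-to-end by
`scripts/acceptance.R`.

## Pipeline

For each locus (and each requested locus combination) the pipeline is:

1. **Complete deletion.** Every alignment column containing a gap, `N`,
   or any IUPAC ambiguity code in any row is removed
   (`complete_deletion()`).  Ambiguity codes are treated as missing
   because base-call ambiguity cannot be distinguished from missing data
   downstream; this is recorded as a package decision since upstream
   handling of heterozygous calls is a wet-lab matter.
2. **Composite-likelihood distances.** Pairwise distances in expected
   substitutions/site under the TN93 model, with the rate parameters
   estimated *once* from substitution counts pooled over all sequence
   pairs (`pool_substitution_counts()`, `estimate_pooled_params()`), then
   held fixed while each pair's divergence is fitted by maximum
   likelihood (`pairwise_distance()`).  This is the standard
   "maximum composite likelihood" scheme for distance-based trees.
3. **Neighbor joining.** Saitou–Nei NJ with the Q criterion
   (`nj_build()`), made fully deterministic (see below), with optional
   nonparametric bootstrap supports (`bootstrap_supports()`, the field
   default is 1000 replicates).  Supports are reported but play no role
   in delimitation.
4. **Delimitation.** Hypothetical species are the *maximal monophyletic
   groups whose members show zero pairwise distance*
   (`zero_distance_clusters()`).  The richness estimate is the number of
   such groups minus the number of known amplification errors
   (`richness_estimate()`).
5. **Scoring** (known-flora mode only): `score_discrimination()` and
   `score_estimation()` produce the accuracy percentages; `faith_pd()`
   adds Faith's phylogenetic diversity of the tree.

`run_survey()` orchestrates all of this per locus/combination and writes
a summary table with one row per analysis, newick trees, and a run
manifest; `compare_loci()` ranks the analyses.

## What "zero distance" means

Delimitation needs a *transitive* notion of "no observed genetic
distance": if A≡B and B≡C the three must form one group.  A numeric
tolerance on fitted distances is not transitive, so the package defines
zero as **bitwise identity of the retained alignment columns** — and,
when binary indel characters are attached, identity of those characters
too.  Fitted distances are exactly 0 precisely for identical rows (the
likelihood is maximized at the boundary), so the matrix invariant
`d == 0 iff rows identical` holds by construction, and the identity
relation, not the numeric matrix, drives clustering.

Indel characters participate only in this identity test, not in the
distance values or the tree: the spacer locus carries species-diagnostic
indels that complete deletion would otherwise erase, and coding them as
presence/absence characters restores that signal as a discrimination
tie-breaker without inventing a gap-cost model for branch lengths.

## Determinism choices in NJ

Three rules make `nj_build()` reproducible to the byte:

* **Tie-break.** Among pairs minimizing Q, the pair whose cluster
  representatives (smallest contained tip id) sort lexicographically
  first is joined.
* **Clamping.** A negative branch length is set to 0 and the deficit is
  moved to its sibling edge, preserving the joined path length.
* **Identity-class collapse.** Samples at distance exactly 0 are
  collapsed to one representative before the joining loop and
  re-attached afterwards as a zero-length fan.  This is not merely an
  optimization: with zero-length pendant edges the Q criterion ties
  *exactly* between joining two identical tips and joining one of them
  with a neighbouring cluster, so floating-point noise can interleave an
  identity class with its neighbours and destroy its monophyly.  The
  collapse guarantees the invariant the delimitation step presupposes —
  every zero-distance class is a clade — while leaving the backbone
  subject to the ordinary NJ rules.  Classes are formed with the full
  identity relation (nucleotides plus indel characters), so
  indel-distinct samples remain separate backbone tips.

Saturated pairs (the pair likelihood increases up to the search bound,
as for near-complementary sequences) yield a flagged undefined distance;
NJ and delimitation refuse such inputs by name rather than propagating
`NaN`.

## Accuracy statistics and rounding

A species is **distinguished** only if its samples form *exactly* one
cluster with no foreign samples.  A species split by intraspecific
variation is not distinguished, yet each of its fragments still counts
toward the richness estimate — this asymmetry is why estimation accuracy
can exceed discrimination accuracy and even 100%.  Percentages are
rounded half away from zero to integers, which reproduces the published
style of reporting (e.g. 22/30 → 73%, 29/41 → 71%); full-precision
columns accompany the integers in the summary table.  One printed table
cell in the source study (a matK value shown as 58% where the stated
formula gives 21/35 = 60%) cannot be reproduced by the formula and is
documented as an inconsistency rather than special-cased.

Amplification errors (contaminant sequences) are supplied as a count —
in real studies they are identified by trace inspection, which is out of
scope; the simulator provides the ground-truth count, and `run_survey()`
derives it from the metadata `error` statuses by default.

## The trnH-psbA inversion

Short intergenic inversions (the canonical case is a 6-bp
TTTTAT/ATAAAA flip) appear as several substitutions within one species
and can split it.  `detect_and_normalize_inversions()` scans windows of
4–30 bp for a minority of rows that carry exactly the reverse complement
of the majority consensus with matching flanks, and flips them back.
Windows are scanned in increasing length so the minimal window is
reported; when complementary flank bases make the boundary ambiguous the
repair is identical either way.  Palindromic windows are skipped (the
orientations are indistinguishable).  Normalization is **off by
default** and enabled per locus: an inversion is a biological
polymorphism discovered post hoc, and silently rewriting sequence data
is a choice the analyst must own.

## Faith's PD

`faith_pd()` sums the branch lengths of the minimal subtree connecting a
tip subset on the *unrooted* tree (an edge contributes iff subset tips
lie on both of its sides).  No root edge is invented, singleton subsets
are refused, and PD of the full tip set equals the total tree length.
The published PD value for the original field data (0.788) requires the
original sequences and is not a desk-scale reproduction target; PD is
validated against a path-union oracle instead.

## The synthetic survey world

`simulate_survey()` generates the artifacts the pipeline reads, with
full ground truth.  The stated world, chosen once:

* ~35 species (two plots of roughly 30–40 in the source study), stem
  counts geometric with mean 3 (~100 stems per plot, mirroring 200
  accessions / 58 species over two plots);
* three loci of 550/850/450 bp with relative rates 0.8/1.0/1.5 — the
  spacer evolves fastest;
* a Yule species tree rescaled to root-to-tip depth 0.15
  substitutions/site, with node heights floored so every interspecific
  divergence is at least `min_split_depth = 0.003` — i.e. at least 20x
  the expected intraspecific pairwise distance, the separation the
  recovery properties assume.  Scientifically this asserts the simulated
  flora consists of barcode-resolvable species spanning multiple genera,
  not an unresolved species complex;
* star-shaped intraspecific variation (no within-species coalescent):
  per-locus fractions (5e-4, 5e-4, 2e-3) of the interspecific scale,
  reflecting near-identity of conspecific plastid barcodes at the coding
  loci and rare intraspecific variants at the spacer;
* lineage-specific amplification failure: per-locus base rates
  (0.02, 0.25, 0.08) with a 5x multiplier on one random clade for the
  matK-like locus, emulating primer universality problems;
* 1% contamination: an "error" sample keeps a sequence, but it is the
  sequence of the most distant species in the plot;
* at the spacer only: a conserved motif region in which carrier species
  (5%) hold a reverse-complemented 6-bp core in a minority of stems, and
  species-level indel polymorphisms (10%) of 3–9 bp.

The generator does **not** emulate alignment error, heteroplasmy,
recombination, within-species coalescence, sequencing quality gradients,
or base-composition heterogeneity among lineages.  A green end-to-end
test therefore establishes that the *analysis* behaves as specified on
data obeying its assumptions — not that any particular real flora will
yield the published accuracies.

## Numerical choices

* Pair divergence is maximized on (1e-9, 20) substitutions/site with
  tolerance 1e-10; hitting 95% of the bound flags saturation.
* Pooled rate maximization is Nelder–Mead on log-parameters; a change
  class with zero observed events makes its kappa unidentifiable and it
  falls back to 1.0 with a flag.
* Distances are computed once per distinct pair of distinct rows and
  expanded, so surveys dominated by identical conspecific stems cost
  far less than their sample count suggests.
* Branch lengths are written with 12 significant digits; bootstrap
  column draws are fixed up front from one seed, making supports
  independent of evaluation order.

## Known limitations

* The composite-likelihood scheme shares one set of rate parameters
  across all pairs; strongly heterogeneous lineups (e.g. mixing
  organellar compartments) violate that pooling.
* No rate-across-sites heterogeneity (no gamma), matching the source
  analysis but limiting fit on saturated data.
* Inversion detection requires the inverted segment to sit in locally
  conserved context; inversions co-occurring with heavy flank variation
  are not found.
* Delimitation is exact-zero: a single sequencing error in one stem
  splits its species.  That is faithful to the method under study, and
  it is why the error-count correction exists, but it makes per-base
  quality control a prerequisite on real data.
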