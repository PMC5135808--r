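---
title: "Predicting recurrent regulatory mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting recurrent regulatory mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrecur)
```

## The problem

Recurrence across patients is the hallmark of cancer driver mutations, but
whole-genome cohorts are still small enough that most recurrent noncoding
sites have simply not been observed twice yet. regrecur implements a
two-part strategy: (1) a statistical test that flags mutations whose local
recurrence is higher than the background mutation process explains, and
(2) a random forest trained on the flagged mutations' regulatory features,
so that mutations which *look like* recurrent regulatory mutations can be
prioritized even before their recurrence is visible.

## The recurrence significance model

For a focal mutation, let `x` be the number of cohort mutation records in
the `w`-bp window centered on it, and estimate the local per-bp mutation
rate `p` from a larger `B`-bp window around the same site. Under the null
hypothesis that mutations arrive as a homogeneous Poisson process, the
number of mutations in the window is `X ~ Poisson(w * p)`, and the site's
recurrence p-value is the upper tail

> P(X >= x),  X ~ Poisson(w p).

Implementation notes, fixed once and documented here:

* **Window centering.** A `w`-bp window on position `pos` covers the
  1-based interval `[pos - floor(w/2), pos + ceil(w/2) - 1]`. Even window
  sizes are therefore left-heavy, and the window always contains `pos`.
  Every window in the package (recurrence, background, revalidation)
  uses this one convention.
* **Self-inclusive counting.** The focal record counts toward `x`, so the
  raw-count thresholds start at `x >= 2` for "seen twice".
  Recurrence is position-based and allele-agnostic, and counts mutation
  records rather than distinct samples.
* **Background estimation.** The background count includes the recurrence
  window's own mutations; this is simpler and slightly conservative (a hot
  site inflates its own background). `exclude_core` inverts this choice.
  At chromosome ends the window is clipped to `[1, length]` and the rate
  renormalized by the clipped width rather than padded.
* **Numerics.** The tail is computed through the Poisson survival function
  (`ppois(x - 1, lambda, lower.tail = FALSE)`), stable to p-values of
  order 1e-300. No multiple-testing correction is applied: the model
  operates on fixed p-value cutoffs (5e-6 by default, with 3e-6 and 3e-4
  as standard alternates), not on a controlled FDR.
* **Background cohort.** When a candidate set (one cancer type) is scored
  against a larger pan-cancer cohort, both the window count and the
  background rate come from the larger cohort; passing the same cohort
  as both arguments scores a cohort against itself.

Training sets are built from the scored records: the true set is everything
passing the threshold (raw count or p-value cutoff), and the false set is a
seeded uniform sample, three times the size of the true set, drawn from
records with raw count exactly 1 whose p-value is above the significance
cutoff. A single RNG stream keyed by the run seed makes the draw
reproducible.

## Target genes, binding sites, and the 35 features

A mutation is *regulatory* here if it can be assigned to a target gene:
first through an enhancer-promoter (EP) pair containing it (highest pairing
score wins; ties break by smaller interval then gene id), otherwise through
a DNase-hypersensitivity correlation map (largest cross-cell-type
correlation wins). Mutations assigned by neither are excluded from all
downstream scoring. The EP map's 500-kb proximity cap is a construction
property of the input map and is not re-checked at lookup time.

Binding-site disruption is assessed by rescanning every position weight
matrix over the windows overlapping the mutated base, in the wild-type and
mutant sequence of the mutation's DHS region. The scanner scores log2
likelihood ratios against a background model and computes **exact**
p-values by dynamic programming over the discretized per-position score
distribution (1e-3-bin quantization of the log-ratios, configurable) — the
same null as the FIMO program, which a precomputed match table can replace
bit-for-bit via `tfbs_scores_from_fimo()`. A motif **gain** means only the
mutant passes the match threshold (`alpha = 1e-4` by default, the
conventional scanning threshold); a **loss**, only the wild type. With

* `diff_Log_Pval_FIMO = (-log10 p_wt) - (-log10 p_mut)` (positive for
  losses; logs are base 10 throughout),
* `avg_Log_Pval_FIMO` their mean, and
* `Gain_or_Loss` in `{-1, 0, +1}`,

the changed PWM with the largest `|diff|` defines the scores when several
change. With no change, `diff` and `Gain_or_Loss` are 0 and `avg` is the
best wild-type match over the whole DHS region (wild-type, not mutant: the
region-wide best site describes the intact regulatory context), whose TF
also supplies the TF-level gene features below.

The full 35-feature panel (see `feature_schema()`):

* **Target-gene features (6)** and **bound-TF features (6)** — for the
  assigned gene and the bound TF respectively: counts of known cancer
  genes at interaction-network distance exactly 1 and exactly 2 (two
  networks; the `_L2` suffix is read as *exactly* two hops, with a
  cumulative `<= 2` reading available by configuration), the sum of
  differential-expression scores over genes reachable within 3 directed
  hops in a regulatory network, and the gene's own differential-expression
  score. The DEG score is `x/(x+1)` with `x = -log10(p)` from a two-sided
  pooled-variance t-test of tumor against normal expression (the classic
  Student test; Welch by configuration), mapping p-values monotonically
  onto `[0, 1)`. When no TF at all is identified the six TF features are 0.
* **Binding-site scores (3)** as above.
* **Cancer-cell epigenetic signals (6)** and **cell-of-origin epigenetic
  signals (11)** — track values at the mutation position (single-base
  lookup by default; a mean over `pos +/- k` is available by
  configuration, since no summarization window is canonical).
* **Genetic signals (3)** — raw bp distance to the nearest
  cancer-associated GWAS SNP on the same chromosome (sentinel 2.5e8 bp
  when the chromosome has none — the order of the largest human
  chromosome, so "no SNP anywhere nearby" sorts beyond every real
  distance); the replication-timing early-to-late ratio
  `(G1B + S1)/(S4 + G2)` (capped at 100 when the denominator is 0); and
  the conservation score at the position.

## The classifier and its evaluation

The classifier is a 1000-tree random forest (the randomForest
implementation with its classification defaults: `mtry = floor(sqrt(35)) =
5`, unlimited depth, bootstrap with replacement, minimum node size 1 — all
configurable). Scores are the proportion of trees voting a mutation into
the recurrent class, each tree voting its own majority leaf.

* **Cross-validation** is 10-repeated 5-fold, label-stratified
  (stratification is this package's choice: it stabilizes the AUC when the
  positive class is around a hundred rows). Each repeat's AUC pools the
  five folds' held-out votes; the reported "average AUC" is the mean over
  repeats. AUC is the tie-aware Mann-Whitney rank statistic.
* **Leave-one-sample-out CV** holds out all mutations of one patient
  sample at a time, re-sampling the false rows of each training set to the
  3:1 ratio with the same seed discipline; an internal assertion guarantees
  no training fold ever contains a held-out sample's rows.
* **Label randomization** permutes the labels uniformly (class balance
  preserved) and should collapse the mean CV AUC to the chance band.
* **Variable importance** is the permutation-based Mean Decrease Accuracy
  on out-of-bag rows per tree, in percentage points — the randomForest
  definition; uninformative features can come out slightly negative.
* **External revalidation** re-checks selected mutations (top raw counts,
  smallest p-values, or top forest votes, ties broken by position) against
  an added disjoint cohort: a selection is *revealed* if at least one new
  mutation falls in the 10- or 100-bp check window. A shared sample id
  between cohorts is treated as leakage and errors. Note that with the
  left-heavy centering a `w`-bp check window reaches `floor(w/2)` bp left
  and `ceil(w/2) - 1` bp right of the site.

## The synthetic study conditions

`make_fixture_bundle()` generates complete, internally consistent inputs at
toy-genome scale. The `default` preset fixes the study conditions used
throughout the package's evaluation:

* 2 chromosomes of 1 Mbp, 20 samples, background 2.5e-4 mutations per bp
  per sample. The pooled density of 5e-3/bp puts the 10-bp window's Poisson
  mean near 0.05 — chosen so the analytic tail bounds give
  `P(X >= 4) ~ 3e-7 << 5e-6` (every multiplicity-4 hotspot is recovered)
  while `P(X >= 3) ~ 2e-5 >> 5e-6` (chance pairs and triples are not).
* 114 hotspots (the reference true-set size) of multiplicity 4-7, each
  spreading its member mutations over distinct samples within +/-2 bp —
  recurrence is cross-patient by construction, though the counting layer
  itself is sample-agnostic.
* Hotspot-linked structure in every resource: a TF consensus site planted
  across each hotspot (so the member substitutions register as motif
  losses), EP pairs covering the hotspots, differential expression of the
  hotspot target genes, cancer genes wired adjacent to them, GWAS SNPs
  100-500 bp away, elevated early-replication fractions, and the
  17-track signal panel boosted at hotspot bins.

The `tiny` preset (1 chromosome x 100 kbp, 8 samples, 3 hotspots) runs the
whole pipeline end-to-end in seconds and backs most tests; `null` removes
hotspots and all feature effects.

`simulate_feature_table()` samples the labeled 35-feature table directly
from per-feature latent Gaussians with standardized mean shifts for true
rows, mapped monotonically onto each feature's natural scale. The default
effect profile concentrates signal where the method's rationale expects it
— chromatin accessibility (0.8 SD), the target gene's network and
expression scores (0.4-0.6 SD), proximity to risk loci (-0.6 SD on the
latent scale), a weak 0.25-SD shift on most remaining features, and none on
conservation or the binding-site change scores. Under this profile the
10-repeated 5-fold CV of the 1000-tree forest lands in the high-0.8s AUC
regime — a constructed analog of, not a claim about, performance on real
cohorts; the `null` profile lands in the chance band.

Problem sizes used by the test suite and the acceptance script — the
default fixture (about 10,000 background records), 456-row feature tables,
10 permutation seeds with full 10x5 CV — were chosen so a complete run
finishes in minutes on one CPU while keeping every class of check at full
strength.

## What the simulations do and do not show

The generator emulates the *shapes* and the *statistical structure* of the
real inputs, not their content: uniform background sequence instead of a
real genome, independent lognormal track bins instead of peak-shaped
coverage, Erdős–Rényi-like networks instead of scale-free interactomes, no
trinucleotide mutation signatures, and no sample-level hypermutators.
Passing tests therefore demonstrate that the statistics are computed
exactly, that the pipeline recovers planted structure under its stated
assumptions, and that the classifier behaves correctly at both the null and
the signal regime — they do not demonstrate classification performance on
real tumor cohorts, which depends on external data this package
deliberately does not ship.

## Degenerate inputs and tie-breaks

Fixed behaviors worth knowing: empty cohorts error at query time; an empty
true set errors while a short false pool warns and uses all of it;
mutations mapping to no gene are dropped with a logged count; a chromosome
absent from a track contributes signal 0; `P(X >= 0) = 1` for any rate;
ties in enhancer choice, DHS correlation, motif-change magnitude, and
top-k selection all break deterministically (score, then interval size or
position, then lexicographic id). Indel rows are skipped on read with a
warning — binding-site rescanning is defined for point substitutions.
Germline filtering matches by position only, the conservative reading when
allele-level provenance is unavailable.

## Known limitations

The local background rate is a windowed estimate, not a covariate model: a
mutation pair in a sparsely mutated region can reach significance under a
narrow background window (1 kbp) that a wide window (100 kbp-1 Mbp) would
reject; choosing `B` is a real modeling decision, and the package defaults
to 10 kbp. The scanner's null assumes an i.i.d. background and scores `N`
bases as background. The forest's vote proportions are not calibrated
probabilities. And the 3:1 false:true ratio is inherited as a fixed design
constant, not tuned.
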