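---
title: "Predicting intra-TAD chromatin interactions from ChIP-seq peak profiles"
author: "chromloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intra-TAD chromatin interactions from ChIP-seq peak profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Three-dimensional chromatin loops — CTCF-mediated architectural loops,
RNA-polymerase-II-mediated transcriptional loops, and the point interactions
visible in Hi-C heatmaps — are expensive to measure directly (ChIA-PET,
in situ Hi-C). One-dimensional ChIP-seq, by contrast, is cheap and abundant.
chromloops asks how far the 1D signal takes us: given peak calls for a panel
of transcription factors and histone modifications, plus TAD (or chromatin
contact domain) coordinates, can a supervised classifier recover which pairs
of genomic segments physically interact?

The central empirical facts the pipeline exploits are that the large
majority of chromatin interactions occur *within* a TAD, and that loop
anchors carry a characteristic epigenomic signature: architectural loop
anchors are enriched for CTCF together with the cohesin-associated factors
SA1, RAD21, SMC3 and ZNF143, while RNAP II loop anchors are enriched for
the active histone marks H3K4me1, H3K4me3 and H3K27ac.

## The pipeline

1. **Binning** (`binGenome`). The genome is tiled into fixed-resolution
   segments: 1 kb for physical-interaction prediction, 5 kb or 40 kb for
   Hi-C heatmaps. The last segment of a chromosome may be short.

2. **Featurization** (`assignPeaks`). Each segment is described by exactly
   two features per assay: the aggregated **peak height** and the bp
   distance between the **peak summit and the segment centre**. When
   several peaks of one assay fall in a segment, the conflict is resolved
   by the *maximum* height at high resolution (≤ 5 kb) and by the *sum* of
   heights at low resolution, reflecting that a 40 kb bin genuinely
   accumulates signal while a 1 kb bin is dominated by its strongest site.
   A segment without a peak gets height 0 and summit distance equal to the
   resolution, so "no peak" is monotonically the weakest observation. The
   resolution also caps the summit distance of peaks whose summit lies in a
   neighbouring segment.

3. **Filtration** (`filterSegments`). Segments lacking a peak of the
   mediating protein (CTCF or RNAP II) are removed, then segments are
   scored by the number of key-feature assays present and thresholded
   (default: at least 1). The score is a presence count rather than a
   height sum: it is threshold-free per assay and directly expresses
   "how many of the anchor-signature assays are available here".
   `thresholdScan` reports retained-segment counts and truth-anchor
   coverage across all thresholds, reproducing the tuning loop a user
   would run on real data. Hi-C heatmaps receive **no filtration**:
   proximity data report most intra-TAD bin pairs as contacting, and the
   mediating proteins of those contacts are diverse.

4. **Candidate pairs** (`candidatePairs`). All `choose(n, 2)` pairs of the
   `n` retained segments of each TAD, and no pairs across TADs. A segment
   belongs to a TAD iff its *centre* lies inside it, so border segments are
   never counted twice; segments outside every TAD do not pair. Each pair
   carries, for every segment feature `f`, the anchor-order-invariant
   encoding `max(f_left, f_right)` and `min(f_left, f_right)`, plus the
   centre-to-centre genomic distance and the ranks of the two segments
   among the TAD's retained segments.

5. **Labels** (`labelPairs`). A pair is positive iff some experimental
   interaction overlaps its left segment with the left anchor *and* its
   right segment with the right anchor (≥ 1 bp on each side; `strict` mode
   requires exact bin identity). The same anchor-overlap rule defines true
   positives at evaluation time. On realistic inputs the positive:negative
   ratio falls in 0.01–0.1.

6. **Learning** (`splitPairs`, `trainModel`, `predictPairs`,
   `evaluatePairs`, `featureReport`). Pairs are split 80/20 at the pair,
   TAD or chromosome level (group levels assign whole groups to one side,
   so cross-TAD and cross-chromosome generalization can be measured without
   leakage). The default classifier is a random forest with 500 trees and
   `sqrt(p)` features per split; SVM and gradient-boosting hooks are
   available behind the same interface. Evaluation reports the confusion
   matrix at a probability cutoff (default 0.5), the rank-statistic AUROC,
   and coverage — the fraction of truth interactions matched on both
   anchors by a positive prediction. `featureReport` returns the forest's
   importance ranking per feature and per assay, a chi-square test of
   independence on feature presence (value > 0) versus label, and the mean
   total anchor peak height in positive versus negative pairs. The
   chi-square dichotomization at zero is most meaningful for height
   features; tables with an expected cell below 5 are flagged rather than
   suppressed. A `excludeDistance` switch trains the distance-free variant
   used to ask how much of the signal is epigenomic rather than positional.

## The Hi-C heatmap route

Raw Hi-C counts cannot be thresholded into interactions directly because
counts are dominated by genomic distance. `scoreContacts` therefore
computes a **distance-stratified score**: within a stratum (one TAD by
default, matching per-TAD training; one chromosome for low-resolution
population heatmaps) and at one bin distance `d`, the score of a contact
with count `c` is the midrank percentile

    dscore(c) = (#{stronger} + 0.5 · #{equal, excluding self}) / N_d

over all `N_d` bin pairs of that stratum-distance, where bin pairs with no
recorded contact enter the population with count 0 (otherwise sparse TADs
would have inflated interaction fractions). Low scores mean stronger than
the distance expectation. The formulation is an interpretation — the
thresholding semantics below is fixed, but the score itself could equally
be a ratio or a p-value; the midrank percentile was chosen because it is
distance-relative by construction, maps onto the `[0, 1]` thresholding
scale, and is invariant to sequencing depth.

`classifyContacts` applies threshold θ (default **0.15**): `interaction`
when `dscore ≤ θ`, `non_interaction` when `dscore ≥ 1 − θ`, `no_class`
otherwise. θ = 0.5 cancels the no-class band. `contactsToPairs` turns
interaction/non-interaction contacts into positive/negative training pairs
and *drops* no-class contacts, which never enter training.

## The synthetic data generator

`simulateBundle` produces complete input bundles — chromosome sizes,
non-overlapping TADs, per-assay narrowPeak tracks, truth interactions
(BEDPE) and a sparse intra-TAD contact map — with the statistical structure
the pipeline assumes, so every stage is testable without external
downloads. What it emulates:

* **Anchor enrichment.** Each assay has a peak-presence probability and a
  log-normal height distribution (heavy right tail, matching ChIP-seq
  signal shape) at anchor segments versus background; enriched assays have
  both higher presence and a shifted log-mean. The mediating protein is
  planted at every loop anchor — ChIA-PET anchors carry their mediator by
  construction.
* **Controlled class balance.** Loops are planted per TAD with
  pairwise-disjoint anchors and a bounded anchor-to-anchor span (real loops
  are short-range relative to their TAD, which also makes genomic distance
  a genuinely informative feature). The number of background
  mediator-positive segments per TAD is then derived by inverting
  `choose(n, 2)` so the positive:negative ratio after filtration lands on
  the profile's target (default 0.05, inside the 0.01–0.1 operating band).
  Infeasible targets fail with the feasible bound.
* **Contacts.** Poisson counts around a power-law distance decay
  (`count_scale · d^(−α)`), multiplied by `loopBoost` at truth-loop bins —
  standard Hi-C phenomenology. Contacts are generated at their own
  resolution (default 5 kb) independent of the segment resolution.

Fixtures: `ctcf_like` (architectural loops, 2 × 5 Mb at 1 kb, ~20 TADs of
300–500 kb, 2 loops per TAD), `rnapii_like` (histone-mark enrichment),
`hic_like` (5 kb segments matching the contact map, for the θ-labelling
route), and `null` (no enrichment anywhere; anchor and background
distributions identical). Everything is reproducible byte-for-byte from
the profile seed.

What the generator does **not** emulate: correlated peak co-occurrence
beyond anchor membership, copy-number and mappability artefacts, ICE-type
matrix biases, inter-chromosomal or inter-TAD contacts, and graded
anchor-ness (anchor signatures are drawn i.i.d. given anchor status). A
classifier that performs well here has been shown to recover the planted
enrichment structure under realistic class imbalance — not to reproduce
published performance on real ENCODE/GEO data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open at every file boundary and converted
  exactly once to the 1-based closed convention of `GRanges`.
* Segment centre is `start + floor(width / 2)`; summit position is
  `peak start + summit offset`, or the peak midpoint when the offset is
  unknown (−1).
* Aggregation ties under `max` are broken towards the closer summit, making
  feature tables independent of peak input order.
* The aggregation auto-rule uses `max` for resolutions ≤ 5 kb and `sum`
  above; the boundary between the stated 5 kb and 40 kb operating points is
  not prescribed anywhere, so the switch sits at the high-resolution edge
  and can always be overridden explicitly.
* Inter-chromosomal interaction records are dropped on read (with a count);
  duplicate contact triples are summed; triples below the diagonal are
  mirrored.
* An empty filtration result is a warning, not an error — downstream stages
  yield zero pairs. A training set with one class is an error naming the
  missing class. θ outside (0, 0.5] and non-positive resolutions are
  errors.
* Splits are reproducible from a seed; serialized models reload to
  bit-identical predictions.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
default fixtures: five replicate seeds of `ctcf_like` (~10 Mb, ~5,000
candidate pairs each) and `null` (~4 Mb at 5 kb, ~58,000 pairs total), plus
one `hic_like` heatmap run (~13,500 scored contacts). These sizes were
chosen so a complete run takes about a minute on one CPU while leaving
every estimate (retention, held-out AUROC, importance ranks, θ-band
fractions) stable across seeds.

## Known limitations

* The distance-score formula is an interpretation (see above); only its
  thresholding semantics is externally fixed.
* The chi-square contingency construction (presence vs label) is one of
  several defensible choices and is reported alongside, not instead of,
  the forest importances.
* Cross-dataset prediction reconciles features by name; assays absent in
  the target dataset are filled with the missing sentinel and a warning,
  which degrades gracefully but cannot conjure absent signal.
* No probability calibration, no hyperparameter search, no distance-matched
  negative sampling: negatives are all intra-TAD non-interacting pairs.

## A minimal run

```{r example, eval = FALSE}
library(chromloops)

b <- simulateBundle(makeFixture("ctcf_like", seed = 1))
sft <- assignPeaks(binGenome(b$chromSizes, 1000), b$peaks, 1000)
keep <- filterSegments(sft, defaultFiltration("ctcf_chiapet"))
pairs <- labelPairs(candidatePairs(sft, keep, b$tads), b$interactions)
sp <- splitPairs(pairs, fraction = 0.8, seed = 1)
model <- trainModel(sp$train, seed = 1)
evaluatePairs(sp$test, predictPairs(model, sp$test), truth = b$interactions)
```

The same flow is available from a shell through the CLI
(`inst/scripts/chromloops`), one subcommand per stage:
`simulate`, `bin-features`, `filter`, `pairs`, `heatmap-score`, `train`,
`predict`, `evaluate`, `report`.
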