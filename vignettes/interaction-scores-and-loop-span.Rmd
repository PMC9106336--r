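---
title: "From 5C counts to interaction scores, and from loop spans to cohesin-dependence"
author: "loopscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 5C counts to interaction scores, and from loop spans to cohesin-dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscore)
```

## The scientific question

Cohesin extrudes chromatin loops and is required to maintain CTCF-anchored
contacts. In post-mitotic neurons, loss of the cohesin subunit RAD21
downregulates a subset of activity-regulated genes (ARGs) while leaving
others — notably the immediate early genes (IEGs) — inducible. The analysis
this package implements asks a structural question: does the genomic span
of the chromatin loops a gene engages in predict whether its expression
depends on cohesin?

Two computational layers answer it:

1. a **5C interaction-score pipeline** that turns ligation-junction
   primer-pair counts into background-corrected, cross-condition-comparable
   loop strengths, used to ask whether individual enhancer-promoter and
   CTCF loops survive cohesin depletion; and
2. a **loop-genomics layer** that classifies Hi-C loop calls (CTCF-anchored,
   enhancer-promoter), measures loop spans, partitions genes into expression
   classes from differential-expression tables, and tests span differences
   between classes.

Both layers run end-to-end on synthetic data generated by the package, so
every stage is testable without external downloads.

## The 5C scoring model

5C queries a designed region through one primer per restriction fragment,
with forward-sense (FOR/LFOR) and reverse-sense (REV/LREV) primers
alternating along the region (the double-alternating design). A read pair
is a valid junction only when one end maps to a forward-sense and the other
to a reverse-sense primer; `tally_pair_counts()` enforces this and counts
discards.

The stages, each a documented function:

| stage | function | key parameters (defaults) |
|---|---|---|
| PCR-bias outlier filter | `remove_outliers()` | removal at >= 8x the 5x5 window median (fold exposed per region; a 100-fold setting suits lower-quality regions) |
| fragment conversion | `primer_to_fragment()` | mean of the 1–2 surviving primer pairs |
| binning | `bin_to_grid()` | 4 kb bins, 12 kb half-open windows around bin centers |
| balancing | `ice_balance()` | iterative correction, tol 1e-8, max 500 iterations, diagonal excluded |
| cross-replicate normalization | `quantile_normalize()` | all replicates of one experimental set |
| expected model | `donut_expected()` | donut half-width 5 bins, excluded center 2 bins, >= 10 informative ring pixels |
| null fit and scores | `fit_logistic()`, `pvalues_and_scores()` | ML logistic on pooled ratios, upper-tail p, floor 1e-12 |
| loop readout | `quantify_loop_pixels()`, `distance_corrected_loop_strength()` | anchor-rectangle means |

The interaction score of a pixel is `-10 * log2(p)`, where p is the
upper-tail probability of its observed/expected ratio under a logistic
distribution fitted to all defined ratios of the matrix: score 0 at p = 1,
10 at p = 0.5, 20 at p = 0.25, capped near 398.6 by the p floor.

### Numerical choices worth knowing

* **Outlier window.** The 5x5 window is truncated at matrix edges and, by
  default, its median is taken over informative (queryable, surviving)
  cells only; `noninformative_as_zero = TRUE` switches to the zero-filled
  alternative. "At least 8-fold higher" is read as `count >= fold * median`
  (non-strict). A zero window median is replaced by an absolute floor
  (default 1) so a sparse matrix is not emptied wholesale. Removal is a
  single pass on the input counts.
* **ICE.** Row-sum-proportional correction with the informative row-sum
  mean as target; rows with no informative mass are excluded, and biases
  are normalized to geometric mean 1, which pins the otherwise
  scale-free balanced matrix and makes it comparable against an
  independent implementation. Near-diagonal exclusion is exposed as
  `min_separation` (default 1 bin: diagonal only).
* **Quantile normalization ties.** Binning with 12 kb windows makes some
  adjacent bins aggregate *identical* fragment sets, so exact value ties
  are structural, not accidental. The default (`ties = "sequential"`)
  breaks ties by position, which guarantees every replicate carries exactly
  the same value distribution afterwards — the property cross-condition
  score comparability rests on. `ties = "average"` gives tied inputs tied
  outputs (average of rank-means) at the cost of exact distribution
  sharing; both conventions agree on tie-free data.
* **Donut reference statistic.** The expected model weights the donut ring
  by a per-diagonal distance-decay reference. On region-scale matrices
  (one to a few hundred bins) an enriched loop's footprint is a visible
  fraction of its diagonal, and a *mean* reference absorbs part of the
  signal being tested (we measured ~17% inflation at a planted 3-fold
  loop, biasing distance-corrected strengths low by ~25–30%). The default
  reference is therefore the per-diagonal *median*, which is robust to the
  handful of enriched pixels; `decay_stat = "mean"` restores the mean for
  genome-scale matrices where loops are negligible per diagonal.
* **Logistic fit.** Maximum likelihood (via `MASS::fitdistr`) from the
  method-of-moments start (location = mean, scale = sd·√3/π), on the
  natural scale by default; `log_scale = TRUE` fits log-ratios. One fit per
  matrix, pooled across distances. Replicate scores are averaged per
  condition for the loop readouts.

## The loop-span analysis

Loops enter as BEDPE calls (anchors ordered, trans entries rejected with a
warning count). A loop is a **CTCF loop** if any CTCF peak overlaps either
anchor (half-open interval semantics throughout; touching intervals do not
overlap). It is an **enhancer-promoter loop** for a gene if the TSS lies in
one anchor and the other anchor holds an enhancer — activity-induced
enhancers only for ARG classes, either kind for constitutive neuronal gene
sets. **Span** is the distance between anchor midpoints (integer floor,
relevant for odd anchor widths).

Expression classes come from curated IEG/LRG membership lists plus
differential-expression tables: an LRG is *downregulated* when adjusted
p < 0.05 with negative log2 fold change in both the silenced (TTX) and 6 h
depolarized (KCl) knockout-vs-control contrasts, *non-deregulated* when
adjusted p > 0.05 in both, and excluded when deregulated in exactly one —
the sign requirement makes "downregulated" mean what it says. Outside the
lists, genes are *inducible* (adjusted p < 0.05 and log2 fold change >= 1 in
either KCl-vs-TTX contrast) or *constitutive* (expressed, adjusted p >= 0.05
in both). The assignment partitions its input: every gene gets exactly one
class or an explicit exclusion reason.

Per-gene span summaries take the longest (or mean) span among qualifying
loops. Genes without loops are included with span 0 for the all-loop and
CTCF-loop analyses and excluded from the enhancer-promoter analysis, where
a zero span cannot stand in for sub-resolution loops. The package follows
this rule literally; the per-gene table flags `had_loop` so users can rerun
with exclusion.

Class comparisons use the two-sample Kolmogorov-Smirnov test. The p-value
follows `stats::ks.test`'s rule: exact small-sample p when `m*n < 10^4`
without ties, asymptotic otherwise, with `exact = FALSE` forcing the
asymptotic Kolmogorov form. We verified by simulation that at the group
sizes of interest (n = 22 vs 43) the asymptotic test rejects at only ~2.8%
for nominal 5%, while the exact p sits near 4%; the exact default is the
calibrated choice at these sizes. Promoter binding enrichment uses the
two-tailed Fisher exact test on a bound/unbound × interest/background
table; the promoter window (TSS ± 2 kb) is a documented default, not a
value inherited from data, so printed odds ratios are fixture properties
rather than reproduction targets.

## What the synthetic data emulate — and what they do not

`simulate_counts()` draws primer-pair counts with expectation

    mu_ij = library_size * Z^-1 * d_ij^-alpha * b_i * b_j * L_ij(condition)

where `d_ij` is the fragment-midpoint distance floored at one bin (no
infinite expectations on the near-diagonal), `b` are log-normal primer
biases shared across replicates (primer efficiency is a design property),
and `L_ij` is the planted loop enrichment. Counts are negative binomial
with dispersion `phi` (variance `mu + phi mu^2`); the study provides no
empirical dispersion, so the default 0.1 is an explicit, configurable
assumption. PCR-bias spikes multiply drawn counts of selected distal pairs,
giving the outlier filter realistic targets.

Condition structure is minimal and multiplicative: inducible loops are
enriched only in stimulated (KCl) conditions, and CTCF (cohesin-dependent)
loops lose their enrichment in RAD21-depleted conditions. The packaged
design plants three archetypes — a short-range inducible enhancer-promoter
loop robust to depletion, a constitutive CTCF domain loop, and a long-range
inducible CTCF-dependent loop — which reproduce the qualitative pattern the
5C readout is meant to resolve.

Loop enrichment is applied to fragment pairs overlapping the same 12 kb
window the binning stage uses around the planted anchor bins. This is
deliberate: binning aggregates a 3x3-bin neighbourhood, so enrichment
confined to a single bin would be diluted to roughly (8 + fold)/9 at the
loop's center pixel; matching the two windows makes the planted fold the
quantity the pipeline should recover.

Scales are desk-sized by choice: one 400 kb region (the study's regions
span 1.2–3.3 Mb), 2 kb mean fragments, 4 kb bins, 2 × 10^6 pairs per
replicate, two replicates for each of four conditions. The gene/loop
fixture plants the comparison groups at the study's sizes (18 IEGs, 22
downregulated LRGs, 43 non-deregulated LRGs) with log-normal spans
(medians 500 kb vs 100 kb for the headline pair, sdlog 0.6, truncated so
anchors stay disjoint and genes independent at 6 Mb spacing).

Passing tests on these data show the pipeline recovers *planted*
multiplicative structure under *independent* negative-binomial noise. They
do not show robustness to what the generator omits: ligation noise and
trans contacts, domain/compartment structure overlaying the decay,
condition-dependent library quality, correlated replicate artifacts, or
mapping ambiguity upstream of the counts. Conclusions about real 5C data
inherit those caveats.

## Problem sizes and runtime

The test suite and the acceptance script run the packaged configurations:
100-bin matrices through the full pipeline (seconds each), 100×100 random
matrices for balancing checks, 120-bin matrices with ten planted loops for
detection, 100-fixture batches for the span-test power and null
calibration, and 4 × 10^4-permutation resampling checks of the KS p-value.
Everything completes in a few minutes on one CPU.

## Known limitations

* The donut expected model omits the lower-left sub-filter of the original
  donut statistic; only the ring background is implemented.
* Scores are reported without multiple-testing correction across pixels,
  matching how interaction scores are used (thresholded, visual, and
  loop-targeted readouts rather than FDR-controlled loop calling).
* Hi-C loop calling itself is out of scope; loops enter as BEDPE calls.
* The outlier filter is single-pass; iterating removal-and-recompute would
  remove more of a dense artifact cluster but is not what the method
  describes.
* All coordinates are treated as co-registered; no genome-build checks.
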