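# loopscore

Chromatin loops anchored by CTCF depend on the cohesin complex; many
enhancer-promoter contacts do not. `loopscore` implements the two
computational analyses needed to connect that distinction to gene
regulation in neurons:

1. a **5C interaction-score pipeline** — from ligation-junction primer-pair
   counts to *Background-corrected Interaction Scores*:
   tally valid (forward × reverse sense) primer pairs → remove PCR-bias
   outliers (counts ≥ 8× the median of the surrounding 5×5 window) →
   average to fragment-fragment counts → bin to 4 kb with 12 kb windows →
   ICE matrix balancing → quantile normalization across replicates → donut
   background expected model → logistic null fit, with
   `score = −10·log2(p)` for the upper-tail p of each pixel's
   observed/expected ratio — plus loop-pixel quantification and
   distance-corrected loop strength;
2. a **loop-genomics layer** — classify loops as CTCF-anchored or
   enhancer-promoter, measure loop spans (anchor-midpoint distance), assign
   genes to expression classes (IEG / downregulated LRG / non-deregulated
   LRG / constitutive / inducible) from differential-expression tables, and
   test span differences between classes (two-sample Kolmogorov-Smirnov)
   and promoter peak-binding enrichment (two-tailed Fisher exact).

A synthetic-data module generates everything the analyses consume —
restriction-fragment designs, double-alternating 5C primers,
multi-replicate multi-condition count matrices with power-law distance
decay, primer biases, negative-binomial noise, planted
constitutive/inducible/cohesin-dependent loops and PCR spikes, and
gene/loop/peak/enhancer fixtures with a planted span-dysregulation
relationship — so the full workflow runs with no external data. All inputs
and outputs use plain-text standards: BED, BEDPE, TSV triplet matrices,
YAML configurations.

## Worked example

The repository is organised as an analysis: three numbered drivers under
`analysis/` run the packaged configurations and write their tables under
`results/`.

```sh
Rscript analysis/01_simulate_5c.R       # synthetic 5C experiment
Rscript analysis/02_interaction_scores.R
Rscript analysis/03_loop_span_analysis.R
```

Step 2 scores the packaged four-condition experiment (TTX-silenced and
KCl-depolarized neurons, each with and without RAD21 depletion; two
replicates each) and quantifies the three planted loop archetypes. Its
distance-corrected loop strengths:

```
 - inducible enhancer-promoter loop: 0.92 (TTX) -> 3.05 (KCl); remains 2.96 under depletion with KCl
 - constitutive CTCF loop: 2.26 intact -> 1.02 cohesin-depleted
 - long-range inducible CTCF loop: 3.09 (KCl) -> 1.09 (KCl, depleted)
```

A strength of 1 means no enrichment over the local distance-matched
background; the short inducible enhancer-promoter contact forms without
cohesin, while CTCF-anchored and long-range loops collapse to background
when cohesin is removed.

Step 3 builds the gene/loop fixture (18 IEGs, 22 downregulated LRGs, 43
non-deregulated LRGs, 60 constitutive genes) and compares loop-span
distributions between classes:

```
headline comparison: downregulated LRGs (n=22, median 570 kb) form longer
longest loops than non-deregulated LRGs (n=43, median 134 kb): D=0.930, p=5.24e-14
```

i.e. the genes whose expression requires cohesin are the ones engaged in
long chromatin loops — the planted relationship, recovered end-to-end from
the emitted BED/BEDPE/TSV files.

The same computations are available programmatically:

```r
library(loopscore)
res <- run_5c_pipeline(packaged_config("fivec"), outdir = "results/02_scores")
res$loop_quantification

ls <- run_loopspan_analysis(packaged_config("loopspan"), outdir = "results/03_loopspan")
subset(ls$ks_stats, filter == "all" & stat == "longest")
```

See `vignettes/interaction-scores-and-loop-span.Rmd` for the model, every
tunable parameter with its default and rationale, what the synthetic data
do and do not emulate, and known limitations.

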