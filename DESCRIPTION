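Package: loopscore
Title: 5C Interaction Scoring and Chromatin Loop-Span Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a chromosome-conformation-capture-carbon-copy (5C)
    interaction-score pipeline (primer-pair tallying, PCR-bias outlier
    filtering, fragment conversion, 4 kb binning, ICE matrix balancing,
    quantile normalization, donut-background expected model, logistic-fit
    p-values and -10*log2(p) interaction scores, loop-pixel quantification)
    together with a chromatin loop genomics layer (CTCF and
    enhancer-promoter loop classification, loop-span metrics, activity-
    regulated gene expression classes, Kolmogorov-Smirnov and Fisher exact
    statistics) for testing whether cohesin-dependence of neuronal gene
    expression scales with chromatin loop length. Ships a synthetic-data
    generator emulating multi-replicate, multi-condition 5C counts with
    distance decay, primer biases, planted loops and PCR spikes, plus
    gene/loop/peak fixtures with planted span-dysregulation structure, so
    the full analysis runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    limma,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
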