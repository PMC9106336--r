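#!/usr/bin/env Rscript
# Step 2 — from raw counts to Background-corrected Interaction Scores.
#
# Runs the full scoring pipeline on the packaged synthetic experiment:
# outlier filter (8-fold over the 5x5 window median), fragment conversion,
# 4 kb binning with 12 kb windows, ICE balancing, quantile normalization
# across all eight replicates, donut-background expected model, logistic
# null fit and -10*log2(p) interaction scores, then quantifies each planted
# loop per condition. Artifacts land in results/02_scores/.

suppressMessages(library(loopscore))

res <- run_5c_pipeline(packaged_config("fivec"), outdir = "results/02_scores")

q <- res$loop_quantification
q$distance_corrected_strength <- round(q$distance_corrected_strength, 2)
q$observed_mean <- round(q$observed_mean, 1)
cat("\nloop quantification (distance-corrected strength by condition):\n")
print(q, row.names = FALSE)

cat("\nreading of the table:\n")
g <- function(loop, cond) q$distance_corrected_strength[q$loop == loop &
                                                          q$condition == cond]
cat(sprintf(" - inducible enhancer-promoter loop: %.2f (TTX) -> %.2f (KCl); remains %.2f under depletion with KCl\n",
            g("ep_short_inducible", "TTX"), g("ep_short_inducible", "KCl"),
            g("ep_short_inducible", "KCl_RAD21dep")))
cat(sprintf(" - constitutive CTCF loop: %.2f intact -> %.2f cohesin-depleted\n",
            g("ctcf_constitutive", "TTX"), g("ctcf_constitutive", "TTX_RAD21dep")))
cat(sprintf(" - long-range inducible CTCF loop: %.2f (KCl) -> %.2f (KCl, depleted)\n",
            g("ep_long_ctcf", "KCl"), g("ep_long_ctcf", "KCl_RAD21dep")))
cat("\nshort inducible enhancer-promoter contacts form without cohesin;\n")
cat("CTCF-anchored and long-range loops require it.\n")
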