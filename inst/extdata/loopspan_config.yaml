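# Packaged loop-span versus dysregulation analysis configuration.
# Class sizes follow the study's comparison groups (18 IEGs, 22 downregulated
# LRGs, 43 non-deregulated LRGs) plus a constitutive background set; loop
# spans are log-normal with class-specific medians.
fixture:
  n_ieg: 18
  n_down_lrg: 22
  n_nondereg_lrg: 43
  n_constitutive: 60
  span_median: {IEG: 5.0e+4, down_lrg: 5.0e+5, nondereg_lrg: 1.0e+5, constitutive: 1.5e+5}
  span_sdlog: 0.6
  ctcf_anchor_frac: 0.7
  enhancer_loop_frac: 0.6
  seed: 1
parameters:
  alpha: 0.05
  induction_lfc: 1
  promoter_halfwidth: 2000
  genotype_contrasts: [nex_ttx, nex_kcl6]
  induction_contrasts: [kcl1_vs_ttx, kcl6_vs_ttx]
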