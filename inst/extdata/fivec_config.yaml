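# Packaged synthetic 5C pipeline configuration.
# One 400 kb region at 4 kb bin resolution, two replicates for each of four
# conditions (silenced / depolarized, with and without cohesin depletion),
# with three planted loop archetypes.
simulation:
  region_length: 400000
  chrom: chrS
  mean_fragment_length: 2000
  decay_exponent: 1.0
  library_size: 2.0e+6
  bias_sd: 0.3
  dispersion: 0.1
  n_spikes: 4
  spike_fold: 50
  n_replicates: 2
  seed: 1
  conditions:
    - {name: TTX,          stimulated: false, depleted: false}
    - {name: KCl,          stimulated: true,  depleted: false}
    - {name: TTX_RAD21dep, stimulated: false, depleted: true}
    - {name: KCl_RAD21dep, stimulated: true,  depleted: true}
  planted_loops:
    - {name: ep_short_inducible, bin_i: 30, bin_j: 38, fold: 4, inducible: true,  ctcf: false}
    - {name: ctcf_constitutive,  bin_i: 10, bin_j: 60, fold: 3, inducible: false, ctcf: true}
    - {name: ep_long_ctcf,       bin_i: 15, bin_j: 85, fold: 4, inducible: true,  ctcf: true}
stages:
  bin_size: 4000
  window: 12000
  outlier_fold: 8
  ice_tol: 1.0e-8
  ice_max_iter: 500
  min_separation: 1
  donut_width: 5
  donut_exclusion: 2
  min_ring_pixels: 10
  p_floor: 1.0e-12
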