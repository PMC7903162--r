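# Example growth configuration: a single parallel bundle in a 10 um cube.
region_size: [10.0, 10.0, 10.0]
target_density: 0.5
radius_mean: 0.5
radius_std: 0.1
dispersion_model: parallel
n_nodes: 100000
cost_weight: 0.2
collapse_initial: 2.0
collapse_increment: 5.0
collapse_max_attempts: 5
n_added: 2500
master_seed: 1
bundles:
- bundle_index: 1
  mean_direction: [0.0, 0.0, 1.0]
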