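# Example generator configuration for `tadlink.R simulate`.
# All log-scale quantities are in log2 units; see ?sim_config for the model.
n_chromosomes: 2
tads_per_chromosome: 10
tad_length: 100000
promoters_per_tad: 5
enhancers_per_tad: 5
tad_activity_sd: 1.0
feature_baseline_mean: 4.0
feature_baseline_sd: 1.0
noise_sd: 0.5
n_samples_per_condition: 6
de_fraction: 0.5
pattern_mixture: [0.7, 0.2, 0.05, 0.05]
effect_size: 2.0
seed: 1
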