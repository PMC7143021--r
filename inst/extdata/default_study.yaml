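# Default study configuration: binary adulteration of acacia honey with
# HFCS F55, HFCS F90 and rape honey.  21 calibration levels (0..100% in 5%
# steps) and 13 prediction levels (0..96% in 8% steps), 3 replicates each.
pure: acacia
adulterants: [hfcs55, hfcs90, rape]
replicates: 3
sigma_shot: 5.0        # per-shot additive noise SD (intensity units)
n_shots: 100           # shots averaged per sample
baseline_level: 1.0    # constant spectral baseline (a.u.)
jitter: 0.1            # per-line amplitude jitter around group levels
grid_step_nm: 0.05
peak_fwhm_nm: 0.30
half_window_nm: 0.25
A_max: 10
cv_folds: 10
ga:
  population_size: 30
  n_generations: 100
  crossover_prob: 0.5
  mutation_prob: 0.01
  fitness_cv_folds: 5
  n_runs: 5
  inclusion_frequency_cutoff: 0.6
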