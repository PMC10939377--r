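seed: 1
output_dir: '.'
log_level: info
model:
  members: 2
  cooperator:
    growth_rate: 0.5
    allee: 0.0
    mu: -0.6
  cheater:
    growth_rate: 0.75
    allee: 0.0
    mu_max: 1.2
    d_protect: 0.2
  regulator:
    growth_rate: 0.75
    allee: 0.0
    phenotype: sensitive
  interactions:
    alpha_AB: 1.9
    alpha_BA: 1.75
    alpha_AC: 0.5
    alpha_BC: 1.0
protocol:
  cycle_hours: 24.0
  n_cycles: 7
  dilution_mode: to_fixed_total
  dilution_factor: 10.0
  initial_total_density: 0.01
  initial_proportions: ~
  antibiotic_window:
  - 72.0
  - 96.0
solver:
  method: lsoda
  rtol: 1.0e-08
  atol: 1.0e-12
  out_dt: 0.1
  extinction_floor: 1.0e-09
  clamp: no
sweep:
  cheater_rate_range:
  - 0.25
  - 0.75
  d_range:
  - 0.0001
  - 0.1
  alpha_ac_range:
  - -1.0
  - 2.0
  alpha_bc_range:
  - -1.0
  - 2.0
  regulator_rate_range:
  - 0.25
  - 1.0
  phenotypes:
  - sensitive
  - detoxifying
  - intrinsic
  n_points: 25
synth:
  noise_sd: 0.02
  replicates: 6
  inoculum_densities:
  - 100000.0
  - 1000000.0
  - 1.0e+07
  - 1.0e+08
  - 1.0e+09
  smx_concentration: 200.0
  clearance_coefficient: 5.0e-08
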