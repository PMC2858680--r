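# Demo configuration for the full synthetic pipeline. Any key omitted here
# falls back to the package default (see ?default_config); unknown keys are
# rejected. Units: hours for times, µm for geometry.
seed: 1
cell_line: SIM
design:
  s_length: 6.0
  n_pulses: 6
  pulse_length: 1.0
arms:
  n_arms: 8
  sigma: 1.0
noise:
  eps_fp: 0.01
  eps_fn: 0.02
  p_unscorable: 0.15
redfish:
  metaphases_per_pulse: 40
  copies_per_arm: 2
intensity:
  snr: 10
  base: 1000
scoring:
  theta_hi: 0.8
  min_total: 200
stats:
  alpha: 0.05
  k: 20
  scheme: bins3
geometry:
  semiaxes: [5.0, 4.0, 1.5]
nuclei:
  spots_per_arm: 50
  ratio_base: 0.2
  ratio_slope: 0.6
  concentration: 10
qfish:
  cv: 0.45
  telomeres_per_allele: 30
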