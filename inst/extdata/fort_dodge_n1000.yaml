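# Sensitivity analysis: total sample size raised to 1,000 at the same
# incidence (1834.9 per 100,000 -> 18 cases, 982 controls); all other
# parameters as in fort_dodge_n436.yaml.
window:
  type: disc
  center: [0.0, 0.0]
  radius: 10.0
n_total: 1000
incidence_per_100k: 1834.9
case_model:
  type: mvn
  centers: [[0.0, 0.0]]
  sigma: 0.83
control_model:
  type: mvn
  centers: [[0.0, 0.0]]
  sigma: 1.67
grid:
  nx: 128
  ny: 128
n_iter: 10000
alpha: 0.05
tails: two
threshold: 0.8
seed: 1
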