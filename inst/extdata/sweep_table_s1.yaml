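# Etiologic sweep: six scenarios crossing incidence rates from the U.S.
# national non-Hodgkin lymphoma rate (20.6 per 100,000) up to the local
# rate near the exposure source (1834.9 per 100,000) with total sample
# sizes of 10,000 and 24,000 (the approximate town population).
window:
  type: disc
  center: [0.0, 0.0]
  radius: 10.0
n_case: 8          # placeholder; the sweep overrides group sizes per row
n_control: 428
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
sweep:
  incidences: [20.6, 917.45, 1834.9]
  n_totals: [10000, 24000]
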