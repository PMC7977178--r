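# Surveillance power calculation: 436 participants within 10 km of the
# exposure point source (incidence 1834.9 per 100,000 -> 8 cases, 428
# controls). Case locations cluster at the source (MVN, sigma 0.83 km);
# control locations approximate the town's population density (MVN,
# sigma 1.67 km). Units: kilometers, source at the origin.
window:
  type: disc
  center: [0.0, 0.0]
  radius: 10.0
n_total: 436
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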