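# Minimal pipeline configuration: one habitat provider and one focal
# species on a 48 x 48 synthetic landscape. Unset keys take the standard
# defaults (SRE q = 0.025, k = 3 with ten repetitions and ten runs,
# ensemble cutoff 0.8, fixed 0.5 binarization threshold).
landscape:
  n_rows: 48
  n_cols: 48
  cell_size: 250
  coarse_factor: 4
species:
  - name: habitat_mangrove
    soil_interval: [0, 200]
    is_habitat: true
    n_presences: 100
    niche:
      bio1: {optimum: 26.75, tolerance: 1.0, weight: 4}
      bio12: {optimum: 3650, tolerance: 700, weight: 2}
    niche_intercept: 3
  - name: bivalve_deep
    soil_interval: [5, 30]
    uses_esrm: true
    n_presences: 130
    niche:
      esrm: {optimum: 1, tolerance: 0.45, weight: 3}
      bdod: {optimum: 78, tolerance: 25, weight: 1.5}
    niche_intercept: 3
scenarios:
  - label: ssp5
    deltas:
      bio1: {mean: 1.8}
      bio12: {mean: -900}
periods:
  - {label: "2050", scale: 1}
seed: 1
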