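# Demonstration run: 2,000-cell synthetic landscape, three virtual species,
# 10 climate simulations reduced to 7 by k-means, reduced ensemble depth
# (8 techniques x 3 repetitions) for quick interactive runs.
seed: 1
landscape:
  n_rows: 50
  n_cols: 40
  edaphic_classes: 10
  n_regions: 5
species:
  boreal:
    linear: {TEM: -3.0, PRE: 0.3, elevation: -0.3}
    quadratic: {TEM: -1.5}
    edaphic: [0.4, -0.4, 0.0, 0.2, 0.0, -0.2, 0.0, 0.0, 0.0, 0.0]
    prevalence_target: 0.45
  temperate:
    linear: {TEM: 3.0, PRATIO: 0.5}
    quadratic: {TEM: -1.5}
    edaphic: [0.0, 0.3, -0.3, 0.0, 0.0, 0.0, 0.2, 0.0, 0.0, 0.0]
    prevalence_target: 0.35
  generalist:
    linear: {PRE: 0.5}
    quadratic: {TEM: -1.0}
    prevalence_target: 0.5
ensemble:
  n_repetitions: 3
scenarios:
  n_simulations: 10
  k_select: 7
thresholds:
  change_threshold: 0.15
  threshold_basis: baseline
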