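# Demo pipeline configuration: two small synthetic datasets with planted
# hand/grip/orientation structure, a transient hand artifact in dataset 2
# only, and every analysis stage enabled at desk scale.
seed: 1
synth:
  n_units: 24
  n_datasets: 2
  trials_per_condition: 8
  baseline_hz: 10
  amplitudes:
    condition_independent: 8
    hand: 5
    grip: 5
    orientation: 5
    "hand:orientation": 2
  artifact:
    dataset: 2
    amplitude: 8
cbpt:
  n_perm: 500
  max_units: 6
dpca:
  n_components: 12
  lambda: 1.0e-06
decode:
  factors: [hand]
  n_iter: 20
  n_shuffles: 20
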