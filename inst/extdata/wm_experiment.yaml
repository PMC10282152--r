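# Reference working-memory experiment: three objects presented in
# sequence, then a partial (colour-only) retrieval cue for the first.
# Omitted fields use the package defaults (device model constants,
# neuron parameters, plasticity rule).
device: {}
plasticity: {}
network:
  n_dims: 3
  n_features_per_dim: 3
  n_conj: 3
protocol:
  init_time: 50
  stim_dur: 100
  rest_dur: 50
  objects:
    - {name: Obj1, features: [1, 1, 1]}   # red, -45 deg, bottom-left
    - {name: Obj2, features: [2, 2, 2]}   # yellow, 0 deg, top-left
    - {name: Obj3, features: [3, 3, 3]}   # blue, +45 deg, top-right
  cues:
    - {object: Obj1, dims: [1]}           # colour-only cue: red
run:
  dt: 0.1
  seed: 1
  snapshot_every: 5
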