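# Example randomization overrides for a real regional dataset: the
# outpatient frequentation indicator is randomized uniformly (instead
# of triangularly) in four named areas. Which cells get the uniform law
# is an expert, dataset-specific choice -- ship your own list.
weights:
  w_tl: 0.9
  w_tr: 1.1
  w_ur: 1.1
uniform_cells:
  - {dmu: Barakaldo, variable: UFrecO8+O10}
  - {dmu: Ercilla, variable: UFrecO8+O10}
  - {dmu: Sestao, variable: UFrecO8+O10}
  - {dmu: Uribe, variable: UFrecO8+O10}
fixed_cells: []
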