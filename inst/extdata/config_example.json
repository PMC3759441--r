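{
  "ligand": "LIG",
  "cofactor": "HEM",
  "reactive_probe": 18,
  "reactive_target": 17,
  "pocket_cutoff": 5.0,
  "include_cofactor": true,
  "d_min": 0.0,
  "d_max": 6.0,
  "width": 0.2,
  "pseudocount": 1.0,
  "min_allowed": 2.9,
  "typing_scheme": "element",
  "seed": 1
}
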