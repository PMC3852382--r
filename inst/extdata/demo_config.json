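{
  "design": "ibm",
  "map": {"n_chromosomes": 3, "markers_per_chromosome": 15, "chrom_length": 100},
  "n_lines": 120,
  "n_intermating_generations": 0,
  "n_blocks": 3,
  "qtl": [
    {"marker": "m02_008", "gate": "attenuator_UV", "effect_uv": 0.8, "effect_drought": 0},
    {"marker": "m03_004", "gate": "AND_gate", "effect_uv": 0, "effect_drought": 0, "effect_combined": 0.9}
  ],
  "seed": 7
}
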