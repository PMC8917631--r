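{
  "name": "default reduced-graph scheme",
  "version": 1,
  "node_types": ["aromatic_ring", "aliphatic_ring", "acyclic"],
  "feature_flags": ["donor", "acceptor"],
  "donor_rule": {
    "elements": ["N", "O", "S"],
    "requires_hydrogen": true
  },
  "acceptor_rule": {
    "elements": ["N", "O"],
    "max_formal_charge": 0,
    "exclude_aromatic_nh": true
  },
  "grouping": {
    "ring_systems": "connected components of ring bonds (fused and spiro systems merge)",
    "acyclic": "connected components of non-ring atoms",
    "merge_single_atom_terminal_substituents": true
  }
}
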