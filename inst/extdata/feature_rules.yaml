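# Default pharmacophore feature perception rules.
# Editable: each entry maps a feature kind to a built-in perceiver.
#   lone_pair_n_o          N/O with a lone pair and no positive charge
#   h_on_n_o               N-H / O-H (hydrogens may be implicit)
#   aliphatic_carbon_group connected non-aromatic carbons with no multiple
#                          bond to a heteroatom, groups of >= min_size
#   halogen_on_aromatic    F/Cl/Br/I attached to an aromatic atom
#   aromatic_ring_centroid one feature per aromatic ring at its centroid;
#                          emitted as aromatic_hydrophobic when the
#                          aromatic-as-hydrophobic amendment is enabled
#   formal_charge          charged atoms -> positive / negative features
version: 1
rules:
  - kind: acceptor
    method: lone_pair_n_o
  - kind: donor
    method: h_on_n_o
  - kind: hydrophobic
    method: aliphatic_carbon_group
    min_size: 3
  - kind: hydrophobic
    method: halogen_on_aromatic
  - kind: aromatic
    method: aromatic_ring_centroid
  - kind: charged
    method: formal_charge
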