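# Default toxicophore / reactive-group SMARTS screen.
# Editable: a conservative set of "warhead" electrophiles and unstable
# groups commonly excluded before screening. Names are reported as the
# machine-readable failure reason (toxicophore:<name>).
version: 1
patterns:
  acyl_halide: "C(=O)[Cl,Br,I]"
  sulfonyl_halide: "S(=O)(=O)[Cl,Br]"
  anhydride: "C(=O)OC(=O)"
  epoxide: "C1OC1"
  aziridine: "C1NC1"
  isocyanate: "N=C=O"
  isothiocyanate: "N=C=S"
  thiol: "[SX2H]"
  peroxide: "[OX2][OX2]"
  hydrazine: "[NX3][NX3]"
  nitroso: "[NX2]=O"
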