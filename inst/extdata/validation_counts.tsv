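stage	actives_in	decoys_in	actives_out	decoys_out
antipharmacophore	211	3122	135	2204
partial	135	2204	111	964
pose	111	964	72	382
field	72	382	65	102
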