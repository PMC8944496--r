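crop,kg_n_ha
alfalfa,150
vetch_oat,60
legumes,60
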