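product,yield_t_ha
barley,2.9
rapeseed,2.5
corn,10.6
soybean,2.9
beetroot_pulp,4.7
cottonseed,4.4
sugarcane_molasses,1.3
palm_oil,3.0
alfalfa,11.3
cereal_straw,2.5
peas,3.5
concentrate,3.8
forage,5.0
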