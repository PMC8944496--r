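product,water_green_m3_t,water_blue_m3_t,water_grey_m3_t,energy_mj_kg
barley,1300,80,130,3.5
soybean,2000,70,30,6.0
corn,950,80,190,4.5
alfalfa,700,150,100,2.5
cereal_straw,400,20,40,1.0
concentrate,1400,100,150,4.8
forage,800,100,90,2.2
peas,1600,30,70,3.8
milk_replacer,2500,300,200,25.0
fertilizer_n,0,5,10,48.0
fertilizer_p2o5,0,3,6,15.0
fertilizer_k2o,0,2,4,9.0
plastic,0,1,2,75.0
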