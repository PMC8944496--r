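name,dm,cp,ndf,adf,omd,starch,ee,ne_mcal_kg,n,p
oat_hay,0.88,0.08,0.58,0.36,0.58,0.02,0.02,1.18,0.0128,0.0022
oat_hay_high_rfv,0.88,0.10,0.50,0.31,0.64,0.02,0.025,1.35,0.0160,0.0024
alfalfa_hay,0.89,0.17,0.44,0.33,0.62,0.02,0.02,1.28,0.0272,0.0026
cereal_straw,0.90,0.04,0.75,0.48,0.45,0.01,0.015,0.80,0.0064,0.0008
vetch_oat_hay,0.88,0.11,0.54,0.35,0.60,0.02,0.02,1.25,0.0176,0.0023
triticale_silage,0.35,0.10,0.55,0.34,0.62,0.04,0.025,1.30,0.0160,0.0028
maize_silage,0.33,0.08,0.45,0.25,0.70,0.28,0.03,1.45,0.0128,0.0022
triticale_pasture,0.20,0.16,0.48,0.28,0.72,0.03,0.03,1.45,0.0256,0.0030
pasture,0.22,0.15,0.50,0.30,0.68,0.02,0.03,1.40,0.0240,0.0030
barley_grain,0.89,0.11,0.20,0.06,0.84,0.52,0.02,1.90,0.0176,0.0035
concentrate_conventional,0.89,0.17,0.22,0.08,0.82,0.40,0.035,1.85,0.0272,0.0050
concentrate_byproduct,0.90,0.16,0.38,0.20,0.70,0.18,0.045,1.60,0.0256,0.0055
soybean_meal,0.89,0.46,0.13,0.08,0.90,0.06,0.02,2.05,0.0736,0.0065
peas,0.89,0.22,0.14,0.07,0.88,0.45,0.015,1.95,0.0352,0.0042
milk_replacer,0.96,0.24,0.00,0.00,0.95,0.00,0.20,2.30,0.0384,0.0070
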