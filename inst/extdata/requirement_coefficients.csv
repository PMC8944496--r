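class,ne_maint_mcal_d,mp_maint_g_d,ne_per_l_milk_mcal,grazing_ne_mcal_km
lactating_high,1.60,45,0.70,0.015
lactating_medium,1.55,45,0.70,0.015
lactating_low,1.50,45,0.70,0.015
non_lactating,1.35,40,0.70,0.015
replacement_0_4,0.55,20,0.70,0.010
replacement_4_12,0.95,30,0.70,0.012
studs,1.70,50,0.70,0.015
offspring,0.40,15,0.70,0.008
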