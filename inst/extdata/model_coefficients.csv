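model,term,beta,beta_se,residual_se,n,r2
replacement_females,(Intercept),-136.7,61.6,271,61,0.65
replacement_females,present_females,0.42,0.04,271,61,0.65
born_offspring,(Intercept),-112.1,89.1,392,61,0.95
born_offspring,present_females,1.91,0.058,392,61,0.95
culled_offspring,(Intercept),91.4,75.8,326,61,0.87
culled_offspring,present_females,0.97,0.049,326,61,0.87
adult_losses,(Intercept),122.6,74.0,189,19,0.80
adult_losses,present_females,0.40,0.04,189,19,0.80
offspring_deaths,(Intercept),-117.2,101.2,377,48,0.59
offspring_deaths,present_females,0.55,0.068,377,48,0.59
feces,(Intercept),523,18.5,59.3,510,0.64
feces,omd_pct,-6.926,0.273,59.3,510,0.64
feces,dmi_g,0.084,0.043,59.3,510,0.64
feces,gp_g,0.57,0.083,59.3,510,0.64
feces,ndf_g,0.269,0.067,59.3,510,0.64
urine,(Intercept),-654.1,74.7,529,313,0.56
urine,n_intake_g,71.3,3.51,529,313,0.56
n_feces,(Intercept),1.30,0.149,1.26,510,0.78
n_feces,n_intake_g,0.24,0.007,1.26,510,0.78
n_urine,(Intercept),1.95,0.482,4.06,313,0.64
n_urine,n_intake_g,0.64,0.021,4.06,313,0.64
n_feces_replacement,(Intercept),0.16,NA,0.065,NA,0.91
n_feces_replacement,n_intake_per_met_wt,0.30,NA,0.065,NA,0.91
n_urine_replacement,(Intercept),-0.0061,NA,0.06,NA,0.98
n_urine_replacement,n_intake_per_met_wt,0.31,NA,0.06,NA,0.98
triticale_yield,(Intercept),-11952,833,669,59,0.93
triticale_yield,height_cm,133.2,4.86,669,59,0.93
triticale_yield,days_to_ear,33.9,3.56,669,59,0.93
triticale_yield,n_basal_kg_ha,62.9,9.21,669,59,0.93
oats_yield,(Intercept),-2632,561.7,1211,35,0.87
oats_yield,height_cm,112,7.4,1211,35,0.87
milk_gv,(Intercept),198.3,NA,24.2,NA,0.89
milk_gv,gv,5.3,NA,24.2,NA,0.89
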