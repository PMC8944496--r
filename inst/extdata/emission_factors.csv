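factor,value,units,source
gwp_ch4,28,kg CO2e per kg CH4,printed
gwp_n2o,298,kg CO2e per kg N2O,printed
ge_mj_per_kg_dm,18.55,MJ GE per kg DM,printed
ch4_energy_mj_per_kg,55.65,MJ per kg CH4,printed
nh3_housing_per_n,0.1,kg NH3 per kg excreted N,printed
nh3_grazing_per_n,0.12,kg NH3 per kg excreted N,printed
n2o_per_nh3_housing,0.0015,kg N2O per kg NH3,printed
n2o_per_grazing_n,0.025,kg N2O per kg (N - NH3) grazing,printed
ef_soil_manure,0.003,kg N2O-N per kg manure N applied,printed (interpreted)
ef_soil_fertilizer,0.01,kg N2O-N per kg fertilizer N,printed (interpreted)
ef_soil_residues,0.01,kg N2O-N per kg residue N,printed (interpreted)
ef_volatilization,0.005,kg N2O-N per kg volatilized N,printed
ef_leaching,0.025,kg N2O-N per kg leached N,printed
ef_fert_manufacture_n2o,0.005,kg N2O per kg purchased fertilizer N,printed
ef_purchased_forage_n2o_n,0.020,kg N2O-N per kg purchased forage N,printed (units assumed)
ef_purchased_conc_n2o_n,0.010,kg N2O-N per kg purchased concentrate N,printed (units assumed)
co2_diesel_l,3.31,kg CO2 per L diesel,printed
co2_electricity_kwh,0.65,kg CO2 per kWh,printed
co2_fert_n,6.2,kg CO2 per kg N,printed
co2_fert_p2o5,0.93,kg CO2 per kg P2O5,printed
co2_fert_k2o,0.51,kg CO2 per kg K2O,printed
co2_forage_kg,0.2,kg CO2 per kg purchased forage,printed
co2_concentrate_kg,0.3,kg CO2 per kg purchased concentrate,printed
co2_plastic_kg,2,kg CO2 per kg plastic,printed
co2_animals_kg_lw,11,kg CO2 per kg purchased live weight,printed
co2_pesticides_ha,22.2,kg CO2 per treated ha,printed
co2_milk_replacer_kg,9.73,kg CO2e per kg milk replacer,printed
co2_soybean_kg,2.98,kg CO2 per kg imported soybean,printed
iluc_kg_co2_m2,0.143,kg CO2 per m2 cultivated per year,printed
diesel_l_per_lu,37,L diesel per LU per year (default),printed
silage_plastic_small_silo_kg,1.3,kg plastic per small silo,printed
silage_plastic_bag_kg_per_t,0.68,kg plastic per t silage,printed
silage_plastic_round_bale_kg_per_t,0.9,kg plastic per t silage,default
silage_co2_per_kg_dm_lost,0.24,kg CO2 per kg DM lost,printed
silage_dm_loss_cereal,0.123,fraction DM lost in cereal silage,printed
silage_dm_loss_maize,0.03,fraction DM lost in maize silage,printed
manure_dm_fraction,0.35,fraction DM of manure,printed
manure_vs_fraction,0.8,kg VS per kg manure DM (default),default
manure_b0_m3_per_kg_vs,0.19,m3 CH4 per kg VS (default),default
manure_mcf,0.015,CH4 conversion factor solid storage (default),default
ch4_density_kg_m3,0.67,kg CH4 per m3,default
biomass_carbon_fraction,0.45,kg C per kg plant DM,printed
manure_c_to_n,13.4,kg C per kg manure N,printed
humification,0.1,fraction of C humified (default),default
stubble_straw_kg_dm_ha,1758,kg DM straw per ha grain cereal,printed
maize_residue_fraction,0.19,fraction of harvest as residue,printed
alfalfa_residue_fraction,0.34,upper fraction of harvest as residue,printed
ap_so2,1,kg SO2e per kg SO2,printed
ap_nox,0.7,kg SO2e per kg NOx,printed
ap_nh3,1.89,kg SO2e per kg NH3,printed
ep_no3,1,kg NO3e per kg NO3,printed
ep_nox,1.35,kg NO3e per kg NOx,printed
ep_nh3,3.64,kg NO3e per kg NH3,printed
ep_po4,10.45,kg NO3e per kg PO4,printed
atmospheric_n_kg_ha,10,kg N per ha per year,printed
n_per_kg_liveweight,0.28,kg N per kg live weight,printed
p_per_kg_liveweight,0.0065,kg P per kg live weight,printed
milk_n_cp_divisor,6.38,kg CP per kg milk N,printed
milk_p_g_per_l,1.3,g P per L milk,printed
milk_density_kg_l,1.034,kg per L milk,default
wool_n_fraction,0.128,kg N per kg wool,printed
wool_p_g_per_kg,0.1,g P per kg wool,printed
grazing_manure_n_pct,0.55,% N in grazing-deposited manure,printed
grazing_manure_p_pct,0.07,% P in grazing-deposited manure,printed
grazing_manure_k_pct,1.1,% K in grazing-deposited manure,printed
housed_manure_n_pct,0.55,% N in housed manure (default),default
housed_manure_p_pct,0.12,% P in housed manure (default),default
housed_manure_k_pct,1.1,% K in housed manure (default),default
bedding_straw_kg_per_female,225,kg bedding straw per female per year,printed
bedding_straw_n_fraction,0.006,kg N per kg straw (default),default
bedding_straw_p_fraction,0.0008,kg P per kg straw (default),default
cleaning_water_l_per_l_milk,2.2,L cleaning water per L milk,printed
drinking_water_l_per_head_day,9,L drinking water per head per day (default),default
diesel_mj_per_l,38.6,MJ per L diesel,default
electricity_mj_per_kwh,3.6,MJ per kWh,default
electricity_kwh_per_ewe_min,0.055,kWh per lactating female per milking minute per year,default
leaching_lambda_cap,0.3,max leached fraction of applied N,default
leaching_lambda_per_mm,0.001,leached fraction per mm drainage,default
fpcm_base,0.25,FPCM formula constant,default
fpcm_fat,0.085,FPCM formula per % fat,default
fpcm_protein,0.035,FPCM formula per % protein,default
allocation_slope,5.7717,AF slope on meat/milk ratio,printed
k_l,0.60,lactation net-energy efficiency,default
mp_assim_sheep,0.58,milk-protein assimilation rate sheep,printed
mp_assim_goat,0.68,milk-protein assimilation rate goat,printed
milk_suckled_l_per_offspring,35,L milk per offspring lactation (35 d x 1 L),printed
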