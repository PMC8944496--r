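breed_group,field,mean,sd
Manchega,total_ha,1013,814
Manchega,arable_ha,164,168
Manchega,fallow_ha,67,93
Manchega,cereal_grain_ha,40,51
Manchega,cereal_forage_ha,35,40
Manchega,maize_ha,6,22.7
Manchega,legumes_ha,16,23.8
Manchega,communal_ha,849,843
Manchega,animals_total,1466,980
Manchega,lactating,838,558
Manchega,replacement,414,326
Manchega,fert_n_kg_ha,24.6,37.2
Manchega,fert_p_kg_ha,7.6,25.7
Manchega,fert_k_kg_ha,5.2,14.9
Manchega,ingested_kg_dm_pf,1025,141
Manchega,purchased_forage_kg_dm_pf,236,119
Manchega,purchased_concentrate_kg_dm_pf,304,44
Manchega,grazing_time_pct,27.9,14.1
Manchega,milk_fpcm_l_pf,307,76
Manchega,liveweight_sold_kg_ha,85.7,180
Manchega,milk_fat_pct,7.0,0.4
Manchega,milk_protein_pct,5.7,0.3
Manchega,milking_time_min,120,30
Foreigners,total_ha,157,215
Foreigners,arable_ha,78,88
Foreigners,fallow_ha,27,48
Foreigners,cereal_grain_ha,28,57
Foreigners,cereal_forage_ha,38,50
Foreigners,maize_ha,0,0
Foreigners,legumes_ha,0,0
Foreigners,communal_ha,79,159
Foreigners,animals_total,1446,1162
Foreigners,lactating,1199,950
Foreigners,replacement,489,470
Foreigners,fert_n_kg_ha,27.7,42.7
Foreigners,fert_p_kg_ha,7.7,11.8
Foreigners,fert_k_kg_ha,7.6,11.8
Foreigners,ingested_kg_dm_pf,1066,166
Foreigners,purchased_forage_kg_dm_pf,338,90
Foreigners,purchased_concentrate_kg_dm_pf,586,143
Foreigners,grazing_time_pct,3.7,7.1
Foreigners,milk_fpcm_l_pf,479,94
Foreigners,liveweight_sold_kg_ha,8664,11072
Foreigners,milk_fat_pct,6.6,0.4
Foreigners,milk_protein_pct,5.5,0.3
Foreigners,milking_time_min,150,30
Florida,total_ha,218,339
Florida,arable_ha,9,7
Florida,fallow_ha,2,2
Florida,cereal_grain_ha,4,3
Florida,cereal_forage_ha,4,6
Florida,maize_ha,0,0
Florida,legumes_ha,0,0
Florida,communal_ha,209,338
Florida,animals_total,228,85
Florida,lactating,122,42
Florida,replacement,52,29
Florida,fert_n_kg_ha,11.1,17.5
Florida,fert_p_kg_ha,0.13,0.21
Florida,fert_k_kg_ha,0.13,0.21
Florida,ingested_kg_dm_pf,790,51
Florida,purchased_forage_kg_dm_pf,250,148
Florida,purchased_concentrate_kg_dm_pf,430,59
Florida,grazing_time_pct,16.5,17.1
Florida,milk_fpcm_l_pf,381,63
Florida,liveweight_sold_kg_ha,671,1057
Florida,milk_fat_pct,5.4,0.4
Florida,milk_protein_pct,3.9,0.3
Florida,milking_time_min,100,25
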