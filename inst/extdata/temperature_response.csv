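season,months,milk_loss_pct_per_c,fat_loss_pct_per_c,protein_loss_pct_per_c
april_may,"4,5",0.10,0.05,0.04
july_august,"7,8",0.45,0.15,0.12
october_november,"10,11",0.14,0.06,0.05
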