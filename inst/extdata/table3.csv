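strain,gram,zone_mean_mm,zone_sd_mm,mic_mean_mg_ml,mic_sd_mg_ml,mbc_mean_mg_ml,mbc_sd_mg_ml
Bacillus subtilis ATCC 6633,positive,11,2,7.81,0.21,15.62,0.62
Staphylococcus aureus ATCC 25923,positive,11,2,7.81,0.19,15.62,0.41
Escherichia coli ATCC 25922,negative,9,1,62.50,1.57,125.00,5.00
Klebsiella pneumoniae ATCC 13883,negative,7,1,NA,NA,NA,NA
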