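# Published cross-site ratios and shares of the same study, as printed.
# Percentages except ghg_difference (t CO2-eq ha-1 yr-1).
quantity,value
reco_ratio_pct,151
gpp_ratio_pct,86
ch4_share_open,57
ch4_share_tree,71
nee_share_open_hollow,64
nee_share_open_hummock,36
reco_share_hummocks_open,64
reco_share_hummocks_tree,62
ghg_difference,1.85
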