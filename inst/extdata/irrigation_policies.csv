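crop,method,trigger_depletion,rice_flooding,bund_height_mm,wetted_fraction
annual_c3,sprinkler,0.45,FALSE,0,1.0
annual_c4,surface,0.50,FALSE,0,1.0
paddy_rice,surface,NA,TRUE,300,1.0
deciduous_perennial,drip,0.35,FALSE,0,0.3
evergreen_perennial,drip,0.30,FALSE,0,0.3
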