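crop,habit,is_rice,tbase,tupp,cc0,ccx,cgc,cdc,zmin,zmax,kcb,wp_star,hi0,p_up,irrigation_threshold,tcrit_heat,wc,cc_min_leafless,co2_sens,profile,planting_doy,harvest_doy
annual_c3,annual,FALSE,0,26,0.05,0.95,0.007,0.005,0.3,1.5,1.05,0.15,0.48,0.55,0.45,32,0.13,0,0.2,deep,280,190
annual_c4,annual,FALSE,8,30,0.05,0.96,0.008,0.006,0.3,1.7,1.05,0.32,0.50,0.60,0.50,35,0.12,0,0.04,deep,120,270
paddy_rice,annual,TRUE,8,30,0.05,0.95,0.009,0.006,0.2,0.6,1.10,0.17,0.43,0.45,NA,36,0.13,0,0.2,shallow,135,265
deciduous_perennial,deciduous_perennial,FALSE,7,30,0.05,0.75,0.010,0.008,1.8,1.8,0.90,0.16,0.55,0.45,0.35,40,0.80,0.10,0.2,deep,100,280
evergreen_perennial,evergreen_perennial,FALSE,10,35,0.05,0.70,0.006,0.004,1.5,1.5,0.80,0.14,0.30,0.50,0.30,42,0.85,0,0.2,deep,1,365
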