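species,tubulin_um,kip2_nm,length_um,length_se,n_length,growth_rate,growth_se,n_growth,catastrophe_freq,catastrophe_se,n_cat,catastrophe_distance,shrink_rate,shrink_se,n_shrink,rescue_freq,rescue_se,n_rescue,rescue_distance
porcine,12,0,1.0,0.1,54,0.32,0.02,172,0.166,0.015,126,1.9,27.6,1.0,130,0.88,0.33,7,32
porcine,12,1,1.0,0.2,75,0.37,0.01,152,0.126,0.012,104,2.9,27.7,0.9,85,0.20,0.14,2,140
porcine,12,2,2.1,0.2,88,0.35,0.01,159,0.135,0.013,115,2.6,29.7,0.9,110,0.54,0.24,5,55
porcine,12,5,5.3,0.2,82,0.62,0.03,77,0.065,0.011,33,10,28.4,1.8,45,2.2,0.7,9,13
porcine,12,10,6.4,0.2,75,0.78,0.03,38,0.043,0.011,16,18,29,4,18,1.8,0.7,6,16
porcine,12,20,7.7,0.3,68,0.99,0.04,36,0.020,0.006,10,50,NA,NA,NA,NA,NA,NA,NA
porcine,12,40,8.8,0.6,26,0.94,0.05,18,0.004,NA,1,235,NA,NA,NA,NA,NA,NA,NA
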