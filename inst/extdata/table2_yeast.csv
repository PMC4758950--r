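species,tubulin_um,kip2_nm,growth_rate,growth_se,n_growth,catastrophe_freq,catastrophe_se,n_cat
yeast,4,0,0.257,0.004,300,0.234,0.017,191
yeast,4,5,0.302,0.005,263,0.137,0.012,141
yeast,4,10,0.353,0.008,146,0.103,0.010,116
yeast,4,20,0.572,0.01,57,0.020,0.006,13
yeast,4,40,0.589,0.012,48,0.009,0.004,5
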