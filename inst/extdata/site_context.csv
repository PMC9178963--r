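watershed,stream,elevation_m,mwmt_baseline_c,mwmt_baseline_se,mwmt_2080_c,ambient_min_c,ambient_max_c,ambient_mean_c,ambient_sd_c,max_treatment_c,climate_treatment_c
Alsea,Fall Creek Tributary,109,16.97,2.53,18.77,16.6,20.0,18.4,1.17,19,22
Siletz,Little Rock Creek,72,18.87,2.64,20.79,16.6,20.0,18.8,0.71,19,22
McKenzie,White Branch Creek,642,15.60,2.62,17.32,10.4,13.4,11.8,0.90,14,19
N. Santiam,N. Santiam River,1127,15.79,2.35,17.52,6.3,10.3,8.1,1.31,14,19
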