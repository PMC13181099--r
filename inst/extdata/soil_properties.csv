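soil_code,ph_h2o,ph_kcl,om_pct,p_ppm,k_ppm,mg_ppm,cec,ec,ca_mg,ca_k,mg_k,texture
MEC,8.4,7.9,1.6,21.0,172.0,206.1,26.7,0.1,15.1,56.7,3.8,Loam (low OM)
BV,7.3,7.3,7.2,187.1,1504.0,696.1,34.5,0.70,4.0,6.5,1.5,Clay loam
COPSA,8.3,7.6,2.5,12.0,204.0,184.0,31.6,0.17,20.1,57.5,2.9,Clay loam
COPMO,8.2,7.4,3.1,44.0,566.0,312.0,34.9,0.13,12.0,21.8,1.8,Clay loam
MBG3,6.3,5.7,5.6,54.0,130.0,96.1,12.9,0.0,15.1,36.3,2.4,Clay loam
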