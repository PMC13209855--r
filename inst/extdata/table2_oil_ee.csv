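formulation,surface_oil_mean,surface_oil_sd,total_oil_mean,total_oil_sd,ee_mean,ee_sd,n
CON,20.48,0.50,35.67,2.08,42.44,4.01,3
ETA,20.57,1.50,31.67,0.58,34.98,5.80,3
EHS,18.48,1.50,30.33,4.73,37.91,11.89,3
STA,16.98,1.00,34.33,3.21,50.11,7.18,3
SHS,13.98,3.00,32.33,1.53,56.59,10.44,3
CTA,17.98,2.00,33.33,1.53,45.93,7.43,3
CHS,15.98,0.04,32.00,1.73,49.97,2.57,3
GTA,18.97,0.04,35.33,4.73,45.60,7.86,3
GHS,16.48,0.50,33.00,3.00,49.88,3.07,3
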