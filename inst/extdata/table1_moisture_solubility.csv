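formulation,moisture_mean,moisture_sd,solubility_mean,solubility_sd,n
CON,3.43,0.06,70.5,5.61,3
ETA,2.45,0.05,75.59,10.95,3
EHS,1.96,0.04,75.84,0.72,3
STA,0.98,0.02,80.83,5.35,3
SHS,1.96,0.04,75.35,10.68,3
CTA,0.98,0.02,81.29,17.11,3
CHS,0.98,0.02,85.81,0.24,3
GTA,1.47,0.03,75.2,0.24,3
GHS,1.96,0.04,80.55,5.52,3
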