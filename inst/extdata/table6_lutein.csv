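formulation,powder_conc_mean,powder_conc_sd,core_conc_mean,core_conc_sd,n
CON,32.85,7.18,99.04,21.64,3
ETA,18.8,3.27,56.68,9.86,3
EHS,17.62,0.54,53.11,1.63,3
STA,20.07,1.02,60.5,3.06,3
SHS,20.62,0.97,62.15,2.91,3
CTA,19.5,2.69,58.79,8.1,3
CHS,20.12,1.45,60.65,4.37,3
GTA,26.82,0.77,80.85,2.31,3
GHS,24.97,0.82,75.27,2.46,3
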