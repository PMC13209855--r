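formulation,valid_n,diameter_mean_um,diameter_sd_um,d10_um,d50_um,d90_um
CON,1090,4.07,1.90,2.06,3.66,6.58
ETA,1040,4.39,2.25,2.22,3.86,7.39
EHS,1135,4.11,2.01,2.16,3.57,6.48
STA,676,4.33,2.52,2.01,3.52,7.54
SHS,796,4.34,2.24,2.11,3.75,7.58
CTA,906,4.38,2.23,2.15,3.81,7.42
CHS,889,4.80,2.28,2.55,4.37,7.56
GTA,1052,4.22,2.00,2.23,3.71,6.63
GHS,1165,3.85,1.94,1.99,3.36,6.36
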