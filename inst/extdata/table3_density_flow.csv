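formulation,bulk_density_mean,bulk_density_sd,tapped_density_mean,tapped_density_sd,ci_mean,ci_sd,hr_mean,hr_sd,n
CON,394.66,5.90,666.00,1.15,40.70,0.88,1.69,0.03,3
ETA,267.65,3.75,506.73,50.59,46.87,4.66,1.90,0.17,3
EHS,260.47,30.96,494.60,4.98,47.35,5.73,1.92,0.21,3
STA,261.74,4.59,524.60,30.28,49.92,2.02,2.00,0.08,3
SHS,264.19,4.08,553.12,27.57,52.08,1.65,2.09,0.07,3
CTA,259.02,1.53,582.59,33.94,55.33,2.36,2.25,0.12,3
CHS,271.58,6.49,540.21,14.67,49.66,0.20,1.99,0.01,3
GTA,271.14,1.88,525.98,13.91,48.36,1.03,1.94,0.04,3
GHS,272.12,2.75,587.45,1.36,53.61,0.47,2.16,0.02,3
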