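formulation,oil_mass,emulsifier_mass,maltodextrin_solution,second_solution,solid_fraction
CON,20,0.4,133,133,0.15
ETA,20,0.4,133,133,0.15
EHS,20,0.4,133,133,0.15
STA,20,0.4,133,133,0.15
SHS,20,0.4,133,133,0.15
CTA,20,0.4,133,133,0.15
CHS,20,0.4,133,133,0.15
GTA,20,0.4,133,133,0.15
GHS,20,0.4,133,133,0.15
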