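complex,vdwaals,e_el,e_pbgb,e_surf
FLT3-M01,-71.17,-51.49,68.69,-8.82
FLT3-M17,-53.77,-21.27,34.20,-6.48
FLT3-D07,-73.59,-48.56,60.95,-9.45
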