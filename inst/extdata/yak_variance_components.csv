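trait,sigma_a2,sigma_e2,h2,se_h2
BW6,37.506,68.848,0.35,0.01
WH6,15.597,11.558,0.57,0.02
BL6,30.752,24.181,0.56,0.02
CG6,23.822,36.526,0.39,0.01
BW12,26.815,83.298,0.24,0.01
WH12,3.941,13.511,0.22,0.02
BL12,1.746,22.812,0.07,0.04
CG12,6.493,19.171,0.25,0.02
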