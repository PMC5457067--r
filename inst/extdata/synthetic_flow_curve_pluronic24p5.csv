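# SYNTHETIC flow curve: noiseless power-law viscosity generated from the
# published 24.5 wt % pluronic F127 constants (n = 0.0511, eta0 = 1.04 Pa.s
# at the 1 1/s reference shear rate). Not measured data.
shear_rate_1/s,viscosity_Pa_s
1,1.04000000000000004
2,0.53874837894901317
5,0.22582951518810906
10,0.11698585117926472
20,0.06060186315653785
50,0.02540274813046311
100,0.01315931670782411
200,0.00681688513886241
500,0.00285746356955260
1000,0.00148024410192531
1500,0.00100748907068591
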