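w_wash,csat_g_per_g
0,0.0752688172043011
0.1,0.03
0.2,0.012
0.3,0.005
0.4,0.002
0.5,0.001
0.6,6e-04
0.7,4e-04
0.8,3e-04
0.9,0.00025
1,2e-04
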