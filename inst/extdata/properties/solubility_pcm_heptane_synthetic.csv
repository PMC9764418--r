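w_wash,csat_g_per_g
0,0.1
0.1,0.05
0.2,0.025
0.3,0.014
0.4,0.011
0.5,0.01
0.6,0.0095
0.7,0.009
0.8,0.0085
0.9,0.008
1,0.0075
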