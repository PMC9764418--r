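w_wash,csat_g_per_g
0,0.136363636363636
0.1,0.18
0.2,0.23
0.3,0.25
0.4,0.24
0.5,0.21
0.6,0.16
0.7,0.11
0.8,0.065
0.9,0.035
1,0.017
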