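w_wash,csat_g_per_g
0,0.136363636363636
0.1,0.155
0.2,0.175
0.3,0.185
0.4,0.19
0.5,0.185
0.6,0.17
0.7,0.14
0.8,0.1
0.9,0.06
1,0.035
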