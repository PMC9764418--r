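w_wash,csat_g_per_g
0,5e-04
0.1,4e-04
0.2,0.00032
0.3,0.00026
0.4,0.00021
0.5,0.00018
0.6,0.00015
0.7,0.00013
0.8,0.00012
0.9,0.00011
1,1e-04
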