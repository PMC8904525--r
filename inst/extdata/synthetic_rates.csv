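age_start,age_end,incidence_rate,mortality_rate
0,20,0.0000005,0.0003
20,25,0.000004,0.0003
25,30,0.000007,0.0004
30,35,0.00001,0.0005
35,40,0.00002,0.0007
40,45,0.00004,0.0011
45,50,0.00008,0.0018
50,55,0.00015,0.0029
55,60,0.00022,0.0047
60,65,0.00030,0.0077
65,70,0.00038,0.0126
70,75,0.00044,0.0215
75,80,0.00048,0.0378
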