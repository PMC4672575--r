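"time_h","mean_Z"
0,35
2,32.7422
4,30.6113
6,28.628
8,26.7471
10,25.0169
12,23.3937
14,21.8805
16,20.4482
18,19.122
20,17.8811
22,16.7194
24,15.6348
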