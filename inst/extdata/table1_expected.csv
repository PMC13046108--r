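loading_vol_pct,brown,orange,black
0,1.1,1.1,1.1
5,1.3,1.2,1.1
10,1.5,1.2,1.2
25,2.1,1.4,1.3
50,3.2,1.8,1.5
75,4.2,2.1,1.6
100,5.3,2.4,1.8
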