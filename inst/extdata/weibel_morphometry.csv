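generation,length_cm,diameter_cm
0,12.0,1.80
1,4.76,1.22
2,1.90,0.83
3,0.76,0.56
4,1.27,0.45
5,1.07,0.35
6,0.90,0.28
7,0.76,0.23
8,0.64,0.186
9,0.54,0.154
10,0.46,0.130
11,0.39,0.109
12,0.33,0.095
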