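1 0.124
2 0.017
3 0.149
4 0.100
5 1.112
6 1.472
7 -999
8 1.096
9 1.326
10 1.497
11 2.341
12 2.028
13 2.092
14 2.098
15 2.380
16 1.751
17 0.055
18 0.055
19 0.010
20 0.053
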