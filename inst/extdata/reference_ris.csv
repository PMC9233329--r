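item_number,ris_mean,ris_sd
1,10.48,7.43
2,5.89,5.14
3,2.48,3.84
4,3.73,4.78
5,3.85,5.04
6,4.41,4.97
7,9.92,6.71
8,8.71,6.65
9,0.76,1.92
10,6.76,5.75
11,3.22,4.13
12,6.89,5.58
13,9.02,6.10
14,15.72,4.74
15,3.47,5.34
16,4.70,5.03
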