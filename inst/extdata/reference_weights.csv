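item_number,level_1,level_2,level_3,level_4,level_5
1,0.0000,0.0262,0.0524,0.0786,0.1048
2,0.0589,0.0442,0.0294,0.0147,0.0000
3,0.0000,0.0062,0.0124,0.0186,0.0248
4,0.0373,0.0280,0.0187,0.0093,0.0000
5,0.0000,0.0096,0.0192,0.0289,0.0385
6,0.0441,0.0330,0.0220,0.0110,0.0000
7,0.0000,0.0248,0.0496,0.0744,0.0992
8,0.0000,0.0218,0.0435,0.0653,0.0871
9,0.0076,0.0057,0.0038,0.0019,0.0000
10,0.0676,0.0507,0.0338,0.0169,0.0000
11,0.0322,0.0241,0.0161,0.0080,0.0000
12,0.0689,0.0517,0.0344,0.0172,0.0000
13,0.0902,0.0677,0.0451,0.0226,0.0000
14,0.1572,0.1179,0.0786,0.0393,0.0000
15,0.0347,0.0260,0.0174,0.0087,0.0000
16,0.0470,0.0352,0.0235,0.0117,0.0000
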