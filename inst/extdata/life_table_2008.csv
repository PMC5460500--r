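age,qx
0,0.007086
1,0.0027876
2,0.0012063
3,0.00062461
4,0.00041069
5,0.00033219
6,0.00030372
7,0.00029414
8,0.0002924
9,0.00029508
10,0.00030192
11,0.00032844
12,0.00036341
13,0.00040894
14,0.00046665
15,0.00053681
16,0.00061769
17,0.0007051
18,0.00079267
19,0.00087273
20,0.00093798
21,0.00098318
22,0.0010066
23,0.0010104
24,0.0010003
25,0.00098417
26,0.00097011
27,0.000965
28,0.00097355
29,0.00099804
30,0.0010387
31,0.0010946
32,0.001164
33,0.0012456
34,0.001338
35,0.0014408
36,0.0015537
37,0.001677
38,0.0018113
39,0.0019574
40,0.0021162
41,0.0022887
42,0.0024762
43,0.0026798
44,0.0029011
45,0.0031414
46,0.0034026
47,0.0036863
48,0.0039946
49,0.0043295
50,0.0046933
51,0.0050886
52,0.005518
53,0.0059846
54,0.0064915
55,0.0070422
56,0.0076405
57,0.0082905
58,0.0089967
59,0.009764
60,0.010598
61,0.011503
62,0.012487
63,0.013556
64,0.014717
65,0.015979
66,0.01735
67,0.018839
68,0.020457
69,0.022215
70,0.024124
71,0.026199
72,0.028453
73,0.030902
74,0.033563
75,0.036453
76,0.039594
77,0.043005
78,0.046712
79,0.050739
80,0.055114
81,0.059868
82,0.065032
83,0.070643
84,0.076738
85,0.08336
86,0.090555
87,0.098372
88,0.10686
89,0.11609
90,0.12611
91,0.137
92,0.14884
93,0.16169
94,0.17565
95,0.19083
96,0.20731
97,0.22522
98,0.24467
99,0.26581
100,1
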