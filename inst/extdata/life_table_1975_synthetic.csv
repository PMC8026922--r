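age,qx
0,0.012
1,3e-04
2,3e-04
3,3e-04
4,3e-04
5,3e-04
6,3e-04
7,3e-04
8,3e-04
9,3e-04
10,3e-04
11,3e-04
12,3e-04
13,3e-04
14,3e-04
15,9e-04
16,9e-04
17,9e-04
18,9e-04
19,9e-04
20,9e-04
21,9e-04
22,9e-04
23,9e-04
24,9e-04
25,9e-04
26,9e-04
27,9e-04
28,9e-04
29,9e-04
30,0.000536738
31,0.000586698
32,0.000641308
33,0.000701002
34,0.000766252
35,0.000837575
36,0.000915537
37,0.00100076
38,0.00109391
39,0.00119573
40,0.00130703
41,0.00142869
42,0.00156167
43,0.00170703
44,0.00186592
45,0.0020396
46,0.00222945
47,0.00243697
48,0.0026638
49,0.00291175
50,0.00318278
51,0.00347904
52,0.00380287
53,0.00415684
54,0.00454376
55,0.0049667
56,0.005429
57,0.00593434
58,0.00648671
59,0.0070905
60,0.00775048
61,0.0084719
62,0.00926047
63,0.0101224
64,0.0110646
65,0.0120946
66,0.0132203
67,0.0144509
68,0.015796
69,0.0172663
70,0.0188734
71,0.0206302
72,0.0225505
73,0.0246495
74,0.0269439
75,0.0294518
76,0.0321932
77,0.0351898
78,0.0384653
79,0.0420456
80,0.0459593
81,0.0502372
82,0.0549133
83,0.0600246
84,0.0656118
85,0.071719
86,0.0783946
87,0.0856916
88,0.0936679
89,0.102387
90,0.111917
91,0.122334
92,0.133721
93,0.146168
94,0.159773
95,0.174645
96,0.190901
97,0.20867
98,0.228093
99,0.249325
100,1
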