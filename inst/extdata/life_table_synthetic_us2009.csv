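age,annual_death_prob
40,0.00178614
41,0.0019413
42,0.00210993
43,0.00229321
44,0.00249242
45,0.00270893
46,0.00294424
47,0.0032
48,0.00347797
49,0.00378009
50,0.00410846
51,0.00446535
52,0.00485324
53,0.00527483
54,0.00573303
55,0.00623105
56,0.00677232
57,0.00736061
58,0.008
59,0.00869494
60,0.00945024
61,0.0102712
62,0.0111634
63,0.0121331
64,0.0131871
65,0.0143326
66,0.0155776
67,0.0169308
68,0.0184015
69,0.02
70,0.0217373
71,0.0236256
72,0.0256779
73,0.0279084
74,0.0303328
75,0.0329677
76,0.0358315
77,0.038944
78,0.042327
79,0.0460038
80,0.05
81,0.0543433
82,0.059064
83,0.0641947
84,0.0697711
85,0.0758319
86,0.0824192
87,0.0895787
88,0.0973601
89,0.105817
90,0.115009
91,0.125
92,0.135858
93,0.14766
94,0.160487
95,0.174428
96,0.18958
97,0.206048
98,0.223947
99,0.2434
100,0.264544
101,0.287524
102,0.3125
103,0.339646
104,0.36915
105,0.401217
106,0.436069
107,0.473949
108,0.51512
109,0.559867
110,1
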