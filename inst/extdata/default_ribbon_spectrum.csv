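"frequency","amplitude"
0,0
1,63.1480352232042
2,103.265135268823
3,143.677006209252
4,183.578634148147
5,218.84698533269
6,273.491582479169
7,312.431154528594
8,156.867578800725
9,8.35980593545155
10,10.220216342204
11,11.8798864270555
12,13.2994343289517
13,13.0157315652086
14,11.4554709428083
15,7.30094338057938
16,1.39186866731407
17,0.811484562774705
18,0.836944262847701
19,0.768974752235583
20,0.660503690381136
21,0.512590247754426
22,0.313684190162738
23,0.157088144380938
24,0.116423536126462
25,0.111102301393973
26,0.0992275603278888
27,0.0847939072513678
28,0.0675964682521676
29,0.0555557341958574
30,0.040778789146567
31,0.0390169538048794
32,0.0397105249803133
33,0.0365182755497186
34,0.0344813437083732
35,0.0344536772434204
36,0.0372437598027723
37,0.0351912052770517
38,0.0324859876123949
39,0.0347533702384688
40,0.0317415570169415
41,0.0344961772094206
42,0.0328792982882145
43,0.0320517626008557
44,0.0341127056952781
45,0.0318784999696575
46,0.03391024221542
47,0.0313429893894622
48,0.0319152042552036
49,0.0325183261008742
50,0.0317860017119479
51,0.0319194630542501
52,0.0301988759878767
53,0.0333837238961606
54,0.0318805487734355
55,0.0308968595404061
56,0.0324639205127674
57,0.0298317373564277
58,0.0337997779023459
59,0.0293940847423165
60,0.0307113419834947
61,0.0321319666462625
62,0.0299412504088036
63,0.0333160263120598
64,0.0282558341605203
65,0.0310651676824376
66,0.0296956460789286
67,0.0302712869310936
68,0.0309029406502991
69,0.0290076997158113
70,0.0306848619378022
71,0.030717202229318
72,0.0279238309203633
73,0.0304917512847567
74,0.0289517768297147
75,0.0302481001121386
76,0.0285454579240157
77,0.0280880616938177
78,0.0300106707640423
79,0.0288002449315166
80,0.0292733924404034
81,0.0273476774353284
82,0.0285792136276771
83,0.0287966485479952
84,0.0287855108606149
85,0.0271009791825487
86,0.0277122118352798
87,0.0280865607760756
88,0.0284829425648567
89,0.0263122874051735
90,0.0278064674344618
91,0.0270035171970692
92,0.0275434404286307
93,0.0265766703933487
94,0.0272753025623542
95,0.0268643165755459
96,0.0266423107936928
97,0.0262642243498909
98,0.0243114008272669
99,0.0273915858815224
100,0.02563058941285
101,0.0274461831259548
102,0.0247369042845124
103,0.0245386620604182
104,0.0266968796771798
105,0.0250180262039444
106,0.0254106584828912
107,0.0245953323100505
108,0.0242434879524014
109,0.0250496029542887
110,0.02343573520116
111,0.0253268962146419
112,0.0240919919928375
113,0.0241484432893101
114,0.0237958757148849
115,0.022946934915228
116,0.0234962014378568
117,0.0235359592753615
118,0.0237032887128785
119,0.0233501032712815
120,0.0221748952989481
121,0.0224313203942063
122,0.0224530873956132
123,0.0217905906166274
124,0.0227232397196354
125,0.0221522799316503
126,0.0222752156858248
127,0.0207804197822699
128,0.0117652812130053
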