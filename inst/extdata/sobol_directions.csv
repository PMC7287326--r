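dim,poly,m1,m2,m3,m4,m5,m6,m7,m8,m9,m10
2,3,1,0,0,0,0,0,0,0,0,0
3,7,1,3,0,0,0,0,0,0,0,0
4,11,1,3,1,0,0,0,0,0,0,0
5,13,1,1,1,0,0,0,0,0,0,0
6,19,1,1,3,3,0,0,0,0,0,0
7,25,1,3,5,13,0,0,0,0,0,0
8,37,1,1,5,5,17,0,0,0,0,0
9,41,1,1,5,5,5,0,0,0,0,0
10,47,1,1,7,11,19,0,0,0,0,0
11,55,1,1,5,1,1,0,0,0,0,0
12,59,1,1,1,3,11,0,0,0,0,0
13,61,1,3,5,5,31,0,0,0,0,0
14,67,1,3,3,9,7,49,0,0,0,0
15,91,1,1,1,15,21,21,0,0,0,0
16,97,1,3,1,13,27,49,0,0,0,0
17,103,1,1,1,15,7,5,0,0,0,0
18,109,1,3,1,15,13,25,0,0,0,0
19,115,1,1,5,5,19,61,0,0,0,0
20,131,1,3,7,11,23,15,103,0,0,0
21,137,1,3,7,13,13,15,69,0,0,0
22,143,1,1,3,13,7,35,63,0,0,0
23,145,1,3,5,9,1,25,53,0,0,0
24,157,1,3,1,13,9,35,107,0,0,0
25,167,1,3,1,5,27,61,31,0,0,0
26,171,1,1,5,11,19,41,61,0,0,0
27,185,1,3,5,3,3,13,69,0,0,0
28,191,1,1,7,13,1,19,1,0,0,0
29,193,1,3,7,5,13,19,59,0,0,0
30,203,1,1,3,9,25,29,41,0,0,0
31,211,1,3,5,13,23,1,55,0,0,0
32,213,1,3,7,3,13,59,17,0,0,0
33,229,1,3,1,3,5,53,69,0,0,0
34,239,1,1,5,5,23,33,13,0,0,0
35,241,1,1,7,7,1,61,123,0,0,0
36,247,1,1,7,9,13,61,49,0,0,0
37,253,1,3,3,5,3,55,33,0,0,0
38,285,1,3,1,15,31,13,49,245,0,0
39,299,1,3,5,15,31,59,63,97,0,0
40,301,1,3,1,11,11,11,77,249,0,0
41,333,1,3,1,11,27,43,71,9,0,0
42,351,1,1,7,15,21,11,81,45,0,0
43,355,1,3,7,3,25,31,65,79,0,0
44,357,1,3,1,1,19,11,3,205,0,0
45,361,1,1,5,9,19,21,29,157,0,0
46,369,1,3,7,11,1,33,89,185,0,0
47,391,1,3,3,3,15,9,79,71,0,0
48,397,1,3,7,11,15,39,119,27,0,0
49,425,1,1,3,1,11,31,97,225,0,0
50,451,1,1,1,3,23,43,57,177,0,0
51,463,1,3,7,7,17,17,37,71,0,0
52,487,1,3,1,5,27,63,123,213,0,0
53,501,1,1,3,5,11,43,53,133,0,0
54,529,1,3,5,5,29,17,47,173,479,0
55,539,1,3,3,11,3,1,109,9,69,0
56,545,1,1,1,5,17,39,23,5,343,0
57,557,1,3,1,5,25,15,31,103,499,0
58,563,1,1,1,11,11,17,63,105,183,0
59,601,1,1,5,11,9,29,97,231,363,0
60,607,1,1,5,15,19,45,41,7,383,0
61,617,1,3,7,7,31,19,83,137,221,0
62,623,1,1,1,3,23,15,111,223,83,0
63,631,1,1,5,13,31,15,55,25,161,0
64,637,1,1,3,13,25,47,39,87,257,0
65,647,1,1,1,11,21,53,125,249,293,0
66,661,1,1,7,11,11,7,57,79,323,0
67,675,1,1,5,5,17,13,81,3,131,0
68,677,1,1,7,13,23,7,65,251,475,0
69,687,1,3,5,1,9,43,3,149,11,0
70,695,1,1,3,13,31,13,13,255,487,0
71,701,1,3,3,1,5,63,89,91,127,0
72,719,1,1,3,3,1,19,123,127,237,0
73,721,1,1,5,7,23,31,37,243,289,0
74,731,1,1,5,11,17,53,117,183,491,0
75,757,1,1,1,5,1,13,13,209,345,0
76,761,1,1,3,15,1,57,115,7,33,0
77,787,1,3,1,11,7,43,81,207,175,0
78,789,1,3,1,1,15,27,63,255,49,0
79,799,1,3,5,3,27,61,105,171,305,0
80,803,1,1,5,3,1,3,57,249,149,0
81,817,1,1,3,5,5,57,15,13,159,0
82,827,1,1,1,11,7,11,105,141,225,0
83,847,1,3,3,5,27,59,121,101,271,0
84,859,1,3,5,9,11,49,51,59,115,0
85,865,1,1,7,1,23,45,125,71,419,0
86,875,1,1,3,5,23,5,105,109,75,0
87,877,1,1,7,15,7,11,67,121,453,0
88,883,1,3,7,3,9,13,31,27,449,0
89,895,1,3,1,15,19,39,39,89,15,0
90,901,1,1,1,1,1,33,73,145,379,0
91,911,1,3,1,15,15,43,29,13,483,0
92,949,1,1,7,3,19,27,85,131,431,0
93,953,1,3,3,3,5,35,23,195,349,0
94,967,1,3,3,7,9,27,39,59,297,0
95,971,1,1,3,9,11,17,13,241,157,0
96,973,1,3,7,15,25,57,33,189,213,0
97,981,1,1,7,1,9,55,73,83,217,0
98,985,1,3,3,13,19,27,23,113,249,0
99,995,1,3,5,3,23,43,3,253,479,0
100,1001,1,1,5,5,11,5,45,117,217,0
101,1019,1,3,3,7,29,37,33,123,147,0
102,1033,1,3,1,15,5,5,37,227,223,459
103,1051,1,1,7,5,5,39,63,255,135,487
104,1063,1,3,1,7,9,7,87,249,217,599
105,1069,1,1,3,13,9,47,7,225,363,247
106,1125,1,3,7,13,19,13,9,67,9,737
107,1135,1,3,5,5,19,59,7,41,319,677
108,1153,1,1,5,3,31,63,15,43,207,789
109,1163,1,1,7,9,13,39,3,47,497,169
110,1221,1,3,1,7,21,17,97,19,415,905
111,1239,1,3,7,1,3,31,71,111,165,127
112,1255,1,1,5,11,1,61,83,119,203,847
113,1267,1,3,3,13,9,61,19,97,47,35
114,1279,1,1,7,7,15,29,63,95,417,469
115,1293,1,3,1,9,25,9,71,57,213,385
116,1305,1,3,5,13,31,47,101,57,39,341
117,1315,1,1,3,3,31,57,125,173,365,551
118,1329,1,3,7,1,13,57,67,157,451,707
119,1341,1,1,1,7,21,13,105,89,429,965
120,1347,1,1,5,9,17,51,45,119,157,141
121,1367,1,3,7,7,13,45,91,9,129,741
122,1387,1,3,7,1,23,57,67,141,151,571
123,1413,1,1,3,11,17,47,93,107,375,157
124,1423,1,3,3,5,11,21,43,51,169,915
125,1431,1,1,5,3,15,55,101,67,455,625
126,1441,1,3,5,9,1,23,29,47,345,595
127,1479,1,3,7,7,5,49,29,155,323,589
128,1509,1,3,3,7,5,41,127,61,261,717
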