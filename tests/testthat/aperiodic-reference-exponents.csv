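spectrum,exponent
1,2.05366234
2,0.61706273
3,2.17001952
4,2.78209176
5,1.76877704
6,2.61723753
7,0.71955187
8,2.85163464
9,1.71771666
10,0.75781954
11,1.70574684
12,2.78867992
13,2.64215350
14,2.44734169
15,1.22068025
16,1.16147644
17,1.34503676
18,2.08467202
19,0.71251785
20,1.89983382
21,1.29625527
22,2.65836690
23,1.22237411
24,0.94044687
25,2.69145561
26,0.97429313
27,1.51490320
28,1.94945498
29,2.89271954
30,1.88691383
31,0.71168353
32,2.93416105
33,1.79899954
34,1.42601276
35,1.50555165
36,1.81518335
37,2.21632953
38,1.90833153
39,1.54037390
40,1.31183202
41,1.84642986
42,0.56724761
43,2.67674379
44,2.75860736
45,2.03925511
46,2.85397243
47,2.34178790
48,1.92047834
49,1.80589027
50,1.06657333
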