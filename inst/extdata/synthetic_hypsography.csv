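# limnobloom 0.1.0
layer_top_m,layer_bottom_m,volume_m3
0,1,44220599.3426195
1,2,43950210.9939113
2,3,43679476.6263754
3,4,43408393.2002343
4,5,43136957.6258497
5,6,42865166.7625149
6,7,42593017.4172133
7,8,42320506.3433335
8,9,42047630.2393527
9,10,41774385.7474617
10,11,41500769.4521571
11,12,41226777.8787797
12,13,40952407.4920074
13,14,40677654.694297
14,15,40402515.8242686
15,16,40126987.1550392
16,17,39851064.8925002
17,18,39574745.1735259
18,19,39298024.0641294
19,20,39020897.5575452
20,21,38743361.5722462
21,22,38465411.9498923
22,23,38187044.4531957
23,24,37908254.7637147
24,25,37629038.4795658
25,26,37349391.1130451
26,27,37069308.0881631
27,28,36788784.7380851
28,29,36507816.3024752
29,30,36226397.9247295
30,31,35944524.6491147
31,32,35662191.4177764
32,33,35379393.0676392
33,34,35096124.3271841
34,35,34812379.8130824
35,36,34528154.0267016
36,37,34243441.3504614
37,38,33958236.0440407
38,39,33672532.2404156
39,40,33386323.9417421
40,41,33099605.0150405
41,42,32812369.1877142
42,43,32524610.0428478
43,44,32236321.0143137
44,45,31947495.3816454
45,46,31658126.2646851
46,47,31368206.6179754
47,48,31077729.2249019
48,49,30786686.691543
49,50,30495071.4402441
50,51,30202875.7028657
51,52,29910091.5137108
52,53,29616710.7021014
53,54,29322724.8845803
54,55,29028125.4567232
55,56,28732903.584524
56,57,28437050.1953435
57,58,28140555.9683685
58,59,27843411.3245796
59,60,27545606.4161622
60,61,27247131.1153516
61,62,26947975.002653
62,63,26648127.3544068
63,64,26347577.1296398
64,65,26046312.9561689
65,66,25744323.1158809
66,67,25441595.5291517
67,68,25138117.7383183
68,69,24833876.8901502
69,70,24528859.7172319
70,71,24223052.5181777
71,72,23916441.1365804
72,73,23609010.9386041
73,74,23300746.7890919
74,75,22991633.0260845
75,76,22681653.4336026
76,77,22370791.212553
77,78,22059028.9495858
78,79,21746348.5837318
79,80,21432731.3706101
80,81,21118157.8439938
81,82,20802607.7744732
82,83,20486060.1249557
83,84,20168493.0026815
84,85,19849883.6074273
85,86,19530208.1754945
86,87,19209441.9190684
87,88,18887558.9604515
88,89,18564532.2606249
89,90,18240333.5415271
90,91,17914933.2013339
91,92,17588300.2219582
92,93,17260402.0678511
93,94,16931204.5750767
94,95,16600671.8294631
95,96,16268766.0324749
96,97,15935447.3532255
97,98,15600673.7648187
98,99,15264400.8628957
99,100,14926581.6639355
100,101,14587166.3804247
101,102,14246102.1695184
102,103,13903332.851198
103,104,13558798.5912057
104,105,13212435.5431236
105,106,12864175.4428618
106,107,12513945.1474557
107,108,12161666.108356
108,109,11807253.767277
109,110,11450616.8599599
110,111,11091656.6097919
111,112,10730265.7888122
112,113,10366327.6179562
113,114,9999714.47093523
114,115,9630286.33632855
115,116,9257888.97931457
116,117,8882351.72671318
117,118,8503484.77463585
118,119,8121075.88414956
119,120,7734886.28241872
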