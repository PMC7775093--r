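# Bundled example kVCT spectrum: 120 kVp Kramers bremsstrahlung hardened by
# 1.25 mm Cu (attenuated with the bundled Cu mu/rho curve), 20-119 keV,
# 1 keV grid, fluence weights normalized to sum to 1.
# Regenerate with filtered_kramers_spectrum(120, 1.25).
"energy_kev","weight"
20,1.7725703e-17
21,2.0505475e-15
22,1.0743748e-13
23,2.9877647e-12
24,4.9812212e-11
25,5.4728194e-10
26,4.2680224e-09
27,2.5058226e-08
28,1.1609986e-07
29,4.409232e-07
30,1.415622e-06
31,3.9793382e-06
32,9.8830569e-06
33,2.2072095e-05
34,4.4982815e-05
35,8.4692631e-05
36,0.00014884784
37,0.00024634731
38,0.00038681331
39,0.0005799228
40,0.00083469293
41,0.001154474
42,0.0015473398
43,0.002016626
44,0.0025633252
45,0.0031860791
46,0.003881314
47,0.0046434878
48,0.0054654122
49,0.0063386151
50,0.0072537145
51,0.0081700438
52,0.0091052384
53,0.010049885
54,0.010994898
55,0.011931688
56,0.01285229
57,0.013749451
58,0.014616686
59,0.015448307
60,0.016239417
61,0.016911475
62,0.017537421
63,0.018115282
64,0.01864362
65,0.019121492
66,0.019548394
67,0.019924217
68,0.020249199
69,0.02052388
70,0.020749059
71,0.020925757
72,0.02105518
73,0.021138687
74,0.021177756
75,0.021173966
76,0.021128964
77,0.021044451
78,0.02092216
79,0.02076384
80,0.020571246
81,0.020288475
82,0.019980505
83,0.019648799
84,0.01929478
85,0.018919825
86,0.018525266
87,0.018112384
88,0.017682416
89,0.017236546
90,0.016775911
91,0.0163016
92,0.015814653
93,0.015316063
94,0.014806777
95,0.014287696
96,0.013759679
97,0.01322354
98,0.012680054
99,0.012129953
100,0.011573934
101,0.010985576
102,0.010396691
103,0.0098076113
104,0.0092186477
105,0.0086300924
106,0.0080422186
107,0.007455282
108,0.0068695217
109,0.0062851609
110,0.005702408
111,0.0051214574
112,0.0045424899
113,0.003965674
114,0.003391166
115,0.0028191111
116,0.0022496438
117,0.0016828885
118,0.0011189602
119,0.00055796487
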