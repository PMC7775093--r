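# XCOM-style elemental mass attenuation compilation (total, with
# coherent scattering), cm^2/g, on the standard published energy grid.
# Values follow the standard Hubbell/Seltzer tabulations; bundled so the
# package is self-contained.  Log-log linear interpolation is intended.
element,energy_kev,mu_over_rho
H,10,0.3854
H,15,0.3764
H,20,0.3695
H,30,0.357
H,40,0.3458
H,50,0.3355
H,60,0.326
H,80,0.3091
H,100,0.2944
H,150,0.2651
H,200,0.2429
H,300,0.2112
H,400,0.1893
H,500,0.1729
H,600,0.1599
H,800,0.1405
H,1000,0.1263
H,1250,0.1129
H,1500,0.1027
H,2000,0.08769
H,3000,0.06921
C,10,2.373
C,15,0.8071
C,20,0.442
C,30,0.2562
C,40,0.2076
C,50,0.1871
C,60,0.1753
C,80,0.161
C,100,0.1514
C,150,0.1347
C,200,0.1229
C,300,0.1066
C,400,0.09546
C,500,0.08715
C,600,0.08058
C,800,0.07076
C,1000,0.06361
C,1250,0.0569
C,1500,0.05179
C,2000,0.04442
C,3000,0.03562
N,10,3.879
N,15,1.236
N,20,0.6178
N,30,0.3066
N,40,0.2288
N,50,0.198
N,60,0.1817
N,80,0.1639
N,100,0.1529
N,150,0.1353
N,200,0.1233
N,300,0.1068
N,400,0.09557
N,500,0.08719
N,600,0.08063
N,800,0.07081
N,1000,0.06364
N,1250,0.05693
N,1500,0.0518
N,2000,0.0445
N,3000,0.03579
O,10,5.952
O,15,1.836
O,20,0.8651
O,30,0.3779
O,40,0.2585
O,50,0.2132
O,60,0.1907
O,80,0.1678
O,100,0.1551
O,150,0.1361
O,200,0.1237
O,300,0.107
O,400,0.09566
O,500,0.08729
O,600,0.0807
O,800,0.07087
O,1000,0.06372
O,1250,0.05697
O,1500,0.05185
O,2000,0.04459
O,3000,0.03597
P,10,40.27
P,15,12.34
P,20,5.358
P,30,1.7
P,40,0.8096
P,50,0.4916
P,60,0.3494
P,80,0.2324
P,100,0.1865
P,150,0.1432
P,200,0.125
P,300,0.1063
P,400,0.09472
P,500,0.08622
P,600,0.07962
P,800,0.06984
P,1000,0.0628
P,1250,0.05619
P,1500,0.0512
P,2000,0.04422
P,3000,0.03576
S,10,50.92
S,15,15.83
S,20,6.708
S,30,2.113
S,40,0.9874
S,50,0.5849
S,60,0.4053
S,80,0.2585
S,100,0.202
S,150,0.1506
S,200,0.1302
S,300,0.1091
S,400,0.09665
S,500,0.08781
S,600,0.08102
S,800,0.07098
S,1000,0.06373
S,1250,0.05697
S,1500,0.05193
S,2000,0.04498
S,3000,0.03655
Ca,10,93.41
Ca,15,30.39
Ca,20,13.06
Ca,30,4.08
Ca,40,1.83
Ca,50,1.019
Ca,60,0.6578
Ca,80,0.3656
Ca,100,0.2577
Ca,150,0.1683
Ca,200,0.1371
Ca,300,0.1105
Ca,400,0.09708
Ca,500,0.08773
Ca,600,0.08066
Ca,800,0.07038
Ca,1000,0.06314
Ca,1250,0.0564
Ca,1500,0.05139
Ca,2000,0.04467
Ca,3000,0.03668
Cu,10,215.9
Cu,15,74.05
Cu,20,33.79
Cu,30,10.92
Cu,40,4.862
Cu,50,2.613
Cu,60,1.593
Cu,80,0.763
Cu,100,0.4584
Cu,150,0.2217
Cu,200,0.1559
Cu,300,0.1119
Cu,400,0.09413
Cu,500,0.08362
Cu,600,0.07625
Cu,800,0.06605
Cu,1000,0.05901
Cu,1250,0.05261
Cu,1500,0.04803
Cu,2000,0.04205
Cu,3000,0.03599
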