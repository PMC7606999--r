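key,value
dose_rate_constant,0.01109
air_kerma_strength,40800
r_min,0.1
r_max,10
r_cm,g
0.100000,0.997488
0.150000,0.997712
0.250000,0.998131
0.400000,0.998684
0.600000,0.999282
0.800000,0.999721
1.000000,1.000000
1.250000,1.000125
1.500000,1.000000
2.000000,0.999003
2.500000,0.997009
3.000000,0.994018
3.500000,0.990030
4.000000,0.985045
5.000000,0.972084
6.000000,0.955135
7.000000,0.934197
8.000000,0.909272
9.000000,0.880359
10.000000,0.847458
r_cm,phi_an
0.100000,0.921143
0.150000,0.926119
0.250000,0.935017
0.400000,0.946095
0.600000,0.957474
0.800000,0.965904
1.000000,0.972150
1.250000,0.977732
1.500000,0.981568
2.000000,0.986017
2.500000,0.988119
3.000000,0.989111
3.500000,0.989580
4.000000,0.989802
5.000000,0.989956
6.000000,0.989990
7.000000,0.989998
8.000000,0.990000
9.000000,0.990000
10.000000,0.990000
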