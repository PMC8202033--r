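# element	C
# Z	6
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-37.531225
r_bohr	rho_e_bohr3
1.5000e-03	1.2490e+02
1.5733e-03	1.2484e+02
1.6502e-03	1.2477e+02
1.7309e-03	1.2469e+02
1.8155e-03	1.2461e+02
1.9043e-03	1.2453e+02
1.9974e-03	1.2443e+02
2.0950e-03	1.2433e+02
2.1974e-03	1.2421e+02
2.3049e-03	1.2409e+02
2.4175e-03	1.2396e+02
2.5357e-03	1.2382e+02
2.6597e-03	1.2366e+02
2.7897e-03	1.2349e+02
2.9261e-03	1.2331e+02
3.0691e-03	1.2312e+02
3.2192e-03	1.2291e+02
3.3765e-03	1.2269e+02
3.5416e-03	1.2245e+02
3.7148e-03	1.2220e+02
3.8964e-03	1.2193e+02
4.0868e-03	1.2165e+02
4.2866e-03	1.2135e+02
4.4962e-03	1.2103e+02
4.7160e-03	1.2069e+02
4.9465e-03	1.2034e+02
5.1883e-03	1.1998e+02
5.4420e-03	1.1959e+02
5.7080e-03	1.1919e+02
5.9871e-03	1.1878e+02
6.2797e-03	1.1835e+02
6.5867e-03	1.1790e+02
6.9087e-03	1.1744e+02
7.2465e-03	1.1697e+02
7.6007e-03	1.1647e+02
7.9723e-03	1.1596e+02
8.3620e-03	1.1542e+02
8.7708e-03	1.1487e+02
9.1996e-03	1.1429e+02
9.6493e-03	1.1369e+02
1.0121e-02	1.1306e+02
1.0616e-02	1.1240e+02
1.1135e-02	1.1171e+02
1.1679e-02	1.1098e+02
1.2250e-02	1.1023e+02
1.2849e-02	1.0944e+02
1.3477e-02	1.0862e+02
1.4136e-02	1.0776e+02
1.4827e-02	1.0687e+02
1.5552e-02	1.0594e+02
1.6312e-02	1.0497e+02
1.7109e-02	1.0397e+02
1.7946e-02	1.0294e+02
1.8823e-02	1.0186e+02
1.9743e-02	1.0075e+02
2.0709e-02	9.9599e+01
2.1721e-02	9.8405e+01
2.2783e-02	9.7168e+01
2.3897e-02	9.5887e+01
2.5065e-02	9.4561e+01
2.6290e-02	9.3190e+01
2.7575e-02	9.1772e+01
2.8923e-02	9.0308e+01
3.0337e-02	8.8798e+01
3.1820e-02	8.7240e+01
3.3376e-02	8.5637e+01
3.5008e-02	8.3987e+01
3.6719e-02	8.2292e+01
3.8514e-02	8.0552e+01
4.0397e-02	7.8768e+01
4.2372e-02	7.6940e+01
4.4443e-02	7.5070e+01
4.6616e-02	7.3158e+01
4.8894e-02	7.1206e+01
5.1285e-02	6.9215e+01
5.3792e-02	6.7188e+01
5.6422e-02	6.5126e+01
5.9180e-02	6.3033e+01
6.2073e-02	6.0911e+01
6.5107e-02	5.8763e+01
6.8290e-02	5.6593e+01
7.1629e-02	5.4404e+01
7.5130e-02	5.2201e+01
7.8803e-02	4.9988e+01
8.2655e-02	4.7770e+01
8.6696e-02	4.5551e+01
9.0934e-02	4.3336e+01
9.5380e-02	4.1130e+01
1.0004e-01	3.8940e+01
1.0493e-01	3.6769e+01
1.1006e-01	3.4625e+01
1.1544e-01	3.2513e+01
1.2109e-01	3.0438e+01
1.2701e-01	2.8406e+01
1.3322e-01	2.6423e+01
1.3973e-01	2.4494e+01
1.4656e-01	2.2624e+01
1.5372e-01	2.0818e+01
1.6124e-01	1.9082e+01
1.6912e-01	1.7418e+01
1.7739e-01	1.5831e+01
1.8606e-01	1.4325e+01
1.9516e-01	1.2901e+01
2.0470e-01	1.1562e+01
2.1470e-01	1.0310e+01
2.2520e-01	9.1445e+00
2.3621e-01	8.0664e+00
2.4776e-01	7.0749e+00
2.5987e-01	6.1689e+00
2.7257e-01	5.3464e+00
2.8590e-01	4.6050e+00
2.9987e-01	3.9417e+00
3.1453e-01	3.3527e+00
3.2991e-01	2.8341e+00
3.4604e-01	2.3813e+00
3.6295e-01	1.9897e+00
3.8070e-01	1.6544e+00
3.9931e-01	1.3701e+00
4.1883e-01	1.1318e+00
4.3930e-01	9.3445e-01
4.6078e-01	7.7296e-01
4.8330e-01	6.4256e-01
5.0693e-01	5.3869e-01
5.3171e-01	4.5711e-01
5.5771e-01	3.9393e-01
5.8497e-01	3.4566e-01
6.1357e-01	3.0918e-01
6.4356e-01	2.8178e-01
6.7502e-01	2.6113e-01
7.0802e-01	2.4530e-01
7.4263e-01	2.3271e-01
7.7894e-01	2.2212e-01
8.1702e-01	2.1258e-01
8.5696e-01	2.0340e-01
8.9885e-01	1.9412e-01
9.4279e-01	1.8444e-01
9.8888e-01	1.7425e-01
1.0372e+00	1.6350e-01
1.0879e+00	1.5228e-01
1.1411e+00	1.4069e-01
1.1969e+00	1.2889e-01
1.2554e+00	1.1707e-01
1.3168e+00	1.0539e-01
1.3812e+00	9.4033e-02
1.4487e+00	8.3134e-02
1.5195e+00	7.2824e-02
1.5938e+00	6.3201e-02
1.6717e+00	5.4336e-02
1.7534e+00	4.6274e-02
1.8391e+00	3.9034e-02
1.9290e+00	3.2610e-02
2.0233e+00	2.6981e-02
2.1223e+00	2.2105e-02
2.2260e+00	1.7933e-02
2.3348e+00	1.4404e-02
2.4490e+00	1.1453e-02
2.5687e+00	9.0137e-03
2.6943e+00	7.0202e-03
2.8260e+00	5.4099e-03
2.9641e+00	4.1244e-03
3.1090e+00	3.1103e-03
3.2610e+00	2.3201e-03
3.4204e+00	1.7116e-03
3.5876e+00	1.2486e-03
3.7630e+00	9.0046e-04
3.9470e+00	6.4169e-04
4.1399e+00	4.5162e-04
4.3423e+00	3.1371e-04
4.5546e+00	2.1495e-04
4.7773e+00	1.4521e-04
5.0108e+00	9.6685e-05
5.2558e+00	6.3437e-05
5.5127e+00	4.1001e-05
5.7822e+00	2.6087e-05
6.0649e+00	1.6319e-05
6.3614e+00	1.0018e-05
6.6723e+00	6.0213e-06
6.9985e+00	3.5340e-06
7.3407e+00	2.0211e-06
7.6995e+00	1.1249e-06
8.0759e+00	6.0939e-07
8.4707e+00	3.2181e-07
8.8848e+00	1.6605e-07
9.3192e+00	8.3902e-08
9.7747e+00	4.1527e-08
1.0253e+01	2.0078e-08
1.0754e+01	9.4192e-09
1.1280e+01	4.2425e-09
1.1831e+01	1.8105e-09
1.2409e+01	7.2127e-10
1.3016e+01	2.6424e-10
1.3652e+01	8.7709e-11
1.4320e+01	2.6004e-11
1.5020e+01	6.7905e-12
1.5754e+01	1.5406e-12
1.6524e+01	2.9960e-13
1.7332e+01	4.9336e-14
1.8179e+01	6.8219e-15
1.9068e+01	7.9404e-16
2.0000e+01	8.0005e-17
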