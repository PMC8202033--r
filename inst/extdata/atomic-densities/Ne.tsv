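# element	Ne
# Z	10
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-128.546952
r_bohr	rho_e_bohr3
1.5000e-03	6.0154e+02
1.5733e-03	6.0081e+02
1.6502e-03	6.0002e+02
1.7309e-03	5.9918e+02
1.8155e-03	5.9826e+02
1.9043e-03	5.9728e+02
1.9974e-03	5.9623e+02
2.0950e-03	5.9511e+02
2.1974e-03	5.9391e+02
2.3049e-03	5.9263e+02
2.4175e-03	5.9127e+02
2.5357e-03	5.8984e+02
2.6597e-03	5.8832e+02
2.7897e-03	5.8672e+02
2.9261e-03	5.8504e+02
3.0691e-03	5.8329e+02
3.2192e-03	5.8145e+02
3.3765e-03	5.7953e+02
3.5416e-03	5.7754e+02
3.7148e-03	5.7546e+02
3.8964e-03	5.7332e+02
4.0868e-03	5.7109e+02
4.2866e-03	5.6878e+02
4.4962e-03	5.6639e+02
4.7160e-03	5.6392e+02
4.9465e-03	5.6135e+02
5.1883e-03	5.5868e+02
5.4420e-03	5.5590e+02
5.7080e-03	5.5300e+02
5.9871e-03	5.4998e+02
6.2797e-03	5.4682e+02
6.5867e-03	5.4352e+02
6.9087e-03	5.4006e+02
7.2465e-03	5.3645e+02
7.6007e-03	5.3267e+02
7.9723e-03	5.2872e+02
8.3620e-03	5.2461e+02
8.7708e-03	5.2032e+02
9.1996e-03	5.1586e+02
9.6493e-03	5.1123e+02
1.0121e-02	5.0642e+02
1.0616e-02	5.0143e+02
1.1135e-02	4.9625e+02
1.1679e-02	4.9089e+02
1.2250e-02	4.8534e+02
1.2849e-02	4.7958e+02
1.3477e-02	4.7363e+02
1.4136e-02	4.6746e+02
1.4827e-02	4.6108e+02
1.5552e-02	4.5448e+02
1.6312e-02	4.4766e+02
1.7109e-02	4.4061e+02
1.7946e-02	4.3333e+02
1.8823e-02	4.2583e+02
1.9743e-02	4.1810e+02
2.0709e-02	4.1014e+02
2.1721e-02	4.0195e+02
2.2783e-02	3.9355e+02
2.3897e-02	3.8493e+02
2.5065e-02	3.7609e+02
2.6290e-02	3.6704e+02
2.7575e-02	3.5779e+02
2.8923e-02	3.4835e+02
3.0337e-02	3.3871e+02
3.1820e-02	3.2890e+02
3.3376e-02	3.1891e+02
3.5008e-02	3.0877e+02
3.6719e-02	2.9848e+02
3.8514e-02	2.8806e+02
4.0397e-02	2.7753e+02
4.2372e-02	2.6690e+02
4.4443e-02	2.5620e+02
4.6616e-02	2.4545e+02
4.8894e-02	2.3466e+02
5.1285e-02	2.2386e+02
5.3792e-02	2.1307e+02
5.6422e-02	2.0233e+02
5.9180e-02	1.9165e+02
6.2073e-02	1.8107e+02
6.5107e-02	1.7061e+02
6.8290e-02	1.6031e+02
7.1629e-02	1.5018e+02
7.5130e-02	1.4026e+02
7.8803e-02	1.3057e+02
8.2655e-02	1.2115e+02
8.6696e-02	1.1201e+02
9.0934e-02	1.0318e+02
9.5380e-02	9.4696e+01
1.0004e-01	8.6566e+01
1.0493e-01	7.8813e+01
1.1006e-01	7.1453e+01
1.1544e-01	6.4500e+01
1.2109e-01	5.7964e+01
1.2701e-01	5.1855e+01
1.3322e-01	4.6175e+01
1.3973e-01	4.0926e+01
1.4656e-01	3.6105e+01
1.5372e-01	3.1705e+01
1.6124e-01	2.7718e+01
1.6912e-01	2.4131e+01
1.7739e-01	2.0927e+01
1.8606e-01	1.8087e+01
1.9516e-01	1.5593e+01
2.0470e-01	1.3420e+01
2.1470e-01	1.1544e+01
2.2520e-01	9.9404e+00
2.3621e-01	8.5823e+00
2.4776e-01	7.4432e+00
2.5987e-01	6.4971e+00
2.7257e-01	5.7183e+00
2.8590e-01	5.0828e+00
2.9987e-01	4.5675e+00
3.1453e-01	4.1514e+00
3.2991e-01	3.8152e+00
3.4604e-01	3.5416e+00
3.6295e-01	3.3155e+00
3.8070e-01	3.1242e+00
3.9931e-01	2.9571e+00
4.1883e-01	2.8056e+00
4.3930e-01	2.6632e+00
4.6078e-01	2.5250e+00
4.8330e-01	2.3877e+00
5.0693e-01	2.2492e+00
5.3171e-01	2.1086e+00
5.5771e-01	1.9657e+00
5.8497e-01	1.8211e+00
6.1357e-01	1.6759e+00
6.4356e-01	1.5315e+00
6.7502e-01	1.3893e+00
7.0802e-01	1.2509e+00
7.4263e-01	1.1178e+00
7.7894e-01	9.9100e-01
8.1702e-01	8.7163e-01
8.5696e-01	7.6041e-01
8.9885e-01	6.5789e-01
9.4279e-01	5.6440e-01
9.8888e-01	4.8009e-01
1.0372e+00	4.0488e-01
1.0879e+00	3.3854e-01
1.1411e+00	2.8067e-01
1.1969e+00	2.3072e-01
1.2554e+00	1.8802e-01
1.3168e+00	1.5189e-01
1.3812e+00	1.2159e-01
1.4487e+00	9.6410e-02
1.5195e+00	7.5695e-02
1.5938e+00	5.8827e-02
1.6717e+00	4.5246e-02
1.7534e+00	3.4438e-02
1.8391e+00	2.5942e-02
1.9290e+00	1.9341e-02
2.0233e+00	1.4272e-02
2.1223e+00	1.0418e-02
2.2260e+00	7.5186e-03
2.3348e+00	5.3587e-03
2.4490e+00	3.7674e-03
2.5687e+00	2.6097e-03
2.6943e+00	1.7799e-03
2.8260e+00	1.1948e-03
2.9641e+00	7.8961e-04
3.1090e+00	5.1405e-04
3.2610e+00	3.2982e-04
3.4204e+00	2.0854e-04
3.5876e+00	1.2977e-04
3.7630e+00	7.9276e-05
3.9470e+00	4.7361e-05
4.1399e+00	2.7544e-05
4.3423e+00	1.5522e-05
4.5546e+00	8.4469e-06
4.7773e+00	4.4320e-06
5.0108e+00	2.2452e-06
5.2558e+00	1.1035e-06
5.5127e+00	5.3052e-07
5.7822e+00	2.5206e-07
6.0649e+00	1.1951e-07
6.3614e+00	5.6891e-08
6.6723e+00	2.7174e-08
6.9985e+00	1.2927e-08
7.3407e+00	6.0529e-09
7.6995e+00	2.7550e-09
8.0759e+00	1.2079e-09
8.4707e+00	5.0887e-10
8.8848e+00	2.0725e-10
9.3192e+00	8.2932e-11
9.7747e+00	3.3446e-11
1.0253e+01	1.3981e-11
1.0754e+01	6.1628e-12
1.1280e+01	2.8510e-12
1.1831e+01	1.3507e-12
1.2409e+01	6.3570e-13
1.3016e+01	2.8980e-13
1.3652e+01	1.2580e-13
1.4320e+01	5.1438e-14
1.5020e+01	1.9644e-14
1.5754e+01	6.9486e-15
1.6524e+01	2.2538e-15
1.7332e+01	6.6236e-16
1.8179e+01	1.7399e-16
1.9068e+01	4.0258e-17
2.0000e+01	8.0791e-18
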