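# element	Ni
# Z	28
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1506.216698
r_bohr	rho_e_bohr3
1.5000e-03	1.3734e+04
1.5733e-03	1.3677e+04
1.6502e-03	1.3618e+04
1.7309e-03	1.3556e+04
1.8155e-03	1.3493e+04
1.9043e-03	1.3427e+04
1.9974e-03	1.3358e+04
2.0950e-03	1.3286e+04
2.1974e-03	1.3211e+04
2.3049e-03	1.3133e+04
2.4175e-03	1.3052e+04
2.5357e-03	1.2966e+04
2.6597e-03	1.2877e+04
2.7897e-03	1.2784e+04
2.9261e-03	1.2687e+04
3.0691e-03	1.2586e+04
3.2192e-03	1.2480e+04
3.3765e-03	1.2370e+04
3.5416e-03	1.2256e+04
3.7148e-03	1.2137e+04
3.8964e-03	1.2014e+04
4.0868e-03	1.1887e+04
4.2866e-03	1.1754e+04
4.4962e-03	1.1617e+04
4.7160e-03	1.1475e+04
4.9465e-03	1.1328e+04
5.1883e-03	1.1176e+04
5.4420e-03	1.1019e+04
5.7080e-03	1.0857e+04
5.9871e-03	1.0689e+04
6.2797e-03	1.0516e+04
6.5867e-03	1.0337e+04
6.9087e-03	1.0153e+04
7.2465e-03	9.9633e+03
7.6007e-03	9.7682e+03
7.9723e-03	9.5676e+03
8.3620e-03	9.3617e+03
8.7708e-03	9.1505e+03
9.1996e-03	8.9341e+03
9.6493e-03	8.7127e+03
1.0121e-02	8.4865e+03
1.0616e-02	8.2555e+03
1.1135e-02	8.0202e+03
1.1679e-02	7.7806e+03
1.2250e-02	7.5372e+03
1.2849e-02	7.2902e+03
1.3477e-02	7.0400e+03
1.4136e-02	6.7870e+03
1.4827e-02	6.5315e+03
1.5552e-02	6.2740e+03
1.6312e-02	6.0150e+03
1.7109e-02	5.7551e+03
1.7946e-02	5.4948e+03
1.8823e-02	5.2348e+03
1.9743e-02	4.9756e+03
2.0709e-02	4.7179e+03
2.1721e-02	4.4623e+03
2.2783e-02	4.2095e+03
2.3897e-02	3.9602e+03
2.5065e-02	3.7152e+03
2.6290e-02	3.4750e+03
2.7575e-02	3.2405e+03
2.8923e-02	3.0124e+03
3.0337e-02	2.7912e+03
3.1820e-02	2.5777e+03
3.3376e-02	2.3723e+03
3.5008e-02	2.1757e+03
3.6719e-02	1.9883e+03
3.8514e-02	1.8106e+03
4.0397e-02	1.6428e+03
4.2372e-02	1.4854e+03
4.4443e-02	1.3384e+03
4.6616e-02	1.2020e+03
4.8894e-02	1.0762e+03
5.1285e-02	9.6094e+02
5.3792e-02	8.5605e+02
5.6422e-02	7.6123e+02
5.9180e-02	6.7615e+02
6.2073e-02	6.0036e+02
6.5107e-02	5.3339e+02
6.8290e-02	4.7467e+02
7.1629e-02	4.2360e+02
7.5130e-02	3.7954e+02
7.8803e-02	3.4178e+02
8.2655e-02	3.0963e+02
8.6696e-02	2.8237e+02
9.0934e-02	2.5929e+02
9.5380e-02	2.3972e+02
1.0004e-01	2.2302e+02
1.0493e-01	2.0860e+02
1.1006e-01	1.9592e+02
1.1544e-01	1.8452e+02
1.2109e-01	1.7401e+02
1.2701e-01	1.6405e+02
1.3322e-01	1.5440e+02
1.3973e-01	1.4488e+02
1.4656e-01	1.3537e+02
1.5372e-01	1.2581e+02
1.6124e-01	1.1618e+02
1.6912e-01	1.0651e+02
1.7739e-01	9.6856e+01
1.8606e-01	8.7308e+01
1.9516e-01	7.7968e+01
2.0470e-01	6.8951e+01
2.1470e-01	6.0375e+01
2.2520e-01	5.2352e+01
2.3621e-01	4.4974e+01
2.4776e-01	3.8309e+01
2.5987e-01	3.2393e+01
2.7257e-01	2.7235e+01
2.8590e-01	2.2815e+01
2.9987e-01	1.9095e+01
3.1453e-01	1.6018e+01
3.2991e-01	1.3521e+01
3.4604e-01	1.1535e+01
3.6295e-01	9.9870e+00
3.8070e-01	8.8040e+00
3.9931e-01	7.9132e+00
4.1883e-01	7.2444e+00
4.3930e-01	6.7330e+00
4.6078e-01	6.3225e+00
4.8330e-01	5.9676e+00
5.0693e-01	5.6353e+00
5.3171e-01	5.3045e+00
5.5771e-01	4.9643e+00
5.8497e-01	4.6115e+00
6.1357e-01	4.2480e+00
6.4356e-01	3.8779e+00
6.7502e-01	3.5060e+00
7.0802e-01	3.1374e+00
7.4263e-01	2.7762e+00
7.7894e-01	2.4267e+00
8.1702e-01	2.0929e+00
8.5696e-01	1.7791e+00
8.9885e-01	1.4895e+00
9.4279e-01	1.2279e+00
9.8888e-01	9.9725e-01
1.0372e+00	7.9895e-01
1.0879e+00	6.3293e-01
1.1411e+00	4.9744e-01
1.1969e+00	3.8941e-01
1.2554e+00	3.0492e-01
1.3168e+00	2.3972e-01
1.3812e+00	1.8967e-01
1.4487e+00	1.5112e-01
1.5195e+00	1.2110e-01
1.5938e+00	9.7345e-02
1.6717e+00	7.8280e-02
1.7534e+00	6.2858e-02
1.8391e+00	5.0393e-02
1.9290e+00	4.0408e-02
2.0233e+00	3.2515e-02
2.1223e+00	2.6353e-02
2.2260e+00	2.1574e-02
2.3348e+00	1.7855e-02
2.4490e+00	1.4918e-02
2.5687e+00	1.2541e-02
2.6943e+00	1.0565e-02
2.8260e+00	8.8794e-03
2.9641e+00	7.4170e-03
3.1090e+00	6.1386e-03
3.2610e+00	5.0230e-03
3.4204e+00	4.0583e-03
3.5876e+00	3.2358e-03
3.7630e+00	2.5461e-03
3.9470e+00	1.9775e-03
4.1399e+00	1.5165e-03
4.3423e+00	1.1485e-03
4.5546e+00	8.5870e-04
4.7773e+00	6.3359e-04
5.0108e+00	4.6098e-04
5.2558e+00	3.3041e-04
5.5127e+00	2.3300e-04
5.7822e+00	1.6141e-04
6.0649e+00	1.0963e-04
6.3614e+00	7.2851e-05
6.6723e+00	4.7248e-05
6.9985e+00	2.9834e-05
7.3407e+00	1.8301e-05
7.6995e+00	1.0889e-05
8.0759e+00	6.2786e-06
8.4707e+00	3.5103e-06
8.8848e+00	1.9065e-06
9.3192e+00	1.0092e-06
9.7747e+00	5.2299e-07
1.0253e+01	2.6663e-07
1.0754e+01	1.3427e-07
1.1280e+01	6.6888e-08
1.1831e+01	3.2900e-08
1.2409e+01	1.5879e-08
1.3016e+01	7.4455e-09
1.3652e+01	3.3499e-09
1.4320e+01	1.4265e-09
1.5020e+01	5.6715e-10
1.5754e+01	2.0775e-10
1.6524e+01	6.9234e-11
1.7332e+01	2.0735e-11
1.8179e+01	5.5121e-12
1.9068e+01	1.2841e-12
2.0000e+01	2.5862e-13
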