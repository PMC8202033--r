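# element	O
# Z	8
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-74.622323
r_bohr	rho_e_bohr3
1.5000e-03	3.0408e+02
1.5733e-03	3.0382e+02
1.6502e-03	3.0355e+02
1.7309e-03	3.0325e+02
1.8155e-03	3.0293e+02
1.9043e-03	3.0258e+02
1.9974e-03	3.0220e+02
2.0950e-03	3.0180e+02
2.1974e-03	3.0136e+02
2.3049e-03	3.0088e+02
2.4175e-03	3.0038e+02
2.5357e-03	2.9984e+02
2.6597e-03	2.9926e+02
2.7897e-03	2.9864e+02
2.9261e-03	2.9798e+02
3.0691e-03	2.9729e+02
3.2192e-03	2.9655e+02
3.3765e-03	2.9577e+02
3.5416e-03	2.9496e+02
3.7148e-03	2.9410e+02
3.8964e-03	2.9320e+02
4.0868e-03	2.9226e+02
4.2866e-03	2.9129e+02
4.4962e-03	2.9027e+02
4.7160e-03	2.8922e+02
4.9465e-03	2.8812e+02
5.1883e-03	2.8699e+02
5.4420e-03	2.8582e+02
5.7080e-03	2.8461e+02
5.9871e-03	2.8335e+02
6.2797e-03	2.8204e+02
6.5867e-03	2.8068e+02
6.9087e-03	2.7927e+02
7.2465e-03	2.7779e+02
7.6007e-03	2.7625e+02
7.9723e-03	2.7463e+02
8.3620e-03	2.7294e+02
8.7708e-03	2.7118e+02
9.1996e-03	2.6933e+02
9.6493e-03	2.6740e+02
1.0121e-02	2.6539e+02
1.0616e-02	2.6329e+02
1.1135e-02	2.6110e+02
1.1679e-02	2.5883e+02
1.2250e-02	2.5647e+02
1.2849e-02	2.5402e+02
1.3477e-02	2.5148e+02
1.4136e-02	2.4885e+02
1.4827e-02	2.4613e+02
1.5552e-02	2.4330e+02
1.6312e-02	2.4038e+02
1.7109e-02	2.3735e+02
1.7946e-02	2.3421e+02
1.8823e-02	2.3097e+02
1.9743e-02	2.2761e+02
2.0709e-02	2.2414e+02
2.1721e-02	2.2056e+02
2.2783e-02	2.1686e+02
2.3897e-02	2.1304e+02
2.5065e-02	2.0912e+02
2.6290e-02	2.0508e+02
2.7575e-02	2.0093e+02
2.8923e-02	1.9666e+02
3.0337e-02	1.9229e+02
3.1820e-02	1.8781e+02
3.3376e-02	1.8323e+02
3.5008e-02	1.7855e+02
3.6719e-02	1.7377e+02
3.8514e-02	1.6889e+02
4.0397e-02	1.6393e+02
4.2372e-02	1.5888e+02
4.4443e-02	1.5375e+02
4.6616e-02	1.4856e+02
4.8894e-02	1.4330e+02
5.1285e-02	1.3798e+02
5.3792e-02	1.3262e+02
5.6422e-02	1.2723e+02
5.9180e-02	1.2181e+02
6.2073e-02	1.1638e+02
6.5107e-02	1.1095e+02
6.8290e-02	1.0553e+02
7.1629e-02	1.0013e+02
7.5130e-02	9.4770e+01
7.8803e-02	8.9462e+01
8.2655e-02	8.4219e+01
8.6696e-02	7.9056e+01
9.0934e-02	7.3986e+01
9.5380e-02	6.9023e+01
1.0004e-01	6.4181e+01
1.0493e-01	5.9474e+01
1.1006e-01	5.4915e+01
1.1544e-01	5.0515e+01
1.2109e-01	4.6287e+01
1.2701e-01	4.2240e+01
1.3322e-01	3.8384e+01
1.3973e-01	3.4726e+01
1.4656e-01	3.1274e+01
1.5372e-01	2.8031e+01
1.6124e-01	2.5003e+01
1.6912e-01	2.2190e+01
1.7739e-01	1.9592e+01
1.8606e-01	1.7208e+01
1.9516e-01	1.5035e+01
2.0470e-01	1.3067e+01
2.1470e-01	1.1297e+01
2.2520e-01	9.7182e+00
2.3621e-01	8.3209e+00
2.4776e-01	7.0946e+00
2.5987e-01	6.0280e+00
2.7257e-01	5.1089e+00
2.8590e-01	4.3247e+00
2.9987e-01	3.6622e+00
3.1453e-01	3.1087e+00
3.2991e-01	2.6512e+00
3.4604e-01	2.2775e+00
3.6295e-01	1.9754e+00
3.8070e-01	1.7338e+00
3.9931e-01	1.5423e+00
4.1883e-01	1.3914e+00
4.3930e-01	1.2725e+00
4.6078e-01	1.1784e+00
4.8330e-01	1.1027e+00
5.0693e-01	1.0401e+00
5.3171e-01	9.8615e-01
5.5771e-01	9.3757e-01
5.8497e-01	8.9173e-01
6.1357e-01	8.4676e-01
6.4356e-01	8.0143e-01
6.7502e-01	7.5507e-01
7.0802e-01	7.0741e-01
7.4263e-01	6.5855e-01
7.7894e-01	6.0881e-01
8.1702e-01	5.5866e-01
8.5696e-01	5.0867e-01
8.9885e-01	4.5943e-01
9.4279e-01	4.1153e-01
9.8888e-01	3.6551e-01
1.0372e+00	3.2185e-01
1.0879e+00	2.8095e-01
1.1411e+00	2.4310e-01
1.1969e+00	2.0850e-01
1.2554e+00	1.7724e-01
1.3168e+00	1.4934e-01
1.3812e+00	1.2470e-01
1.4487e+00	1.0319e-01
1.5195e+00	8.4618e-02
1.5938e+00	6.8749e-02
1.6717e+00	5.5344e-02
1.7534e+00	4.4147e-02
1.8391e+00	3.4902e-02
1.9290e+00	2.7356e-02
2.0233e+00	2.1266e-02
2.1223e+00	1.6403e-02
2.2260e+00	1.2558e-02
2.3348e+00	9.5470e-03
2.4490e+00	7.2094e-03
2.5687e+00	5.4103e-03
2.6943e+00	4.0374e-03
2.8260e+00	2.9988e-03
2.9641e+00	2.2197e-03
3.1090e+00	1.6396e-03
3.2610e+00	1.2101e-03
3.4204e+00	8.9342e-04
3.5876e+00	6.6010e-04
3.7630e+00	4.8804e-04
3.9470e+00	3.6089e-04
4.1399e+00	2.6670e-04
4.3423e+00	1.9683e-04
4.5546e+00	1.4499e-04
4.7773e+00	1.0654e-04
5.0108e+00	7.8053e-05
5.2558e+00	5.6953e-05
5.5127e+00	4.1328e-05
5.7822e+00	2.9763e-05
6.0649e+00	2.1222e-05
6.3614e+00	1.4942e-05
6.6723e+00	1.0365e-05
6.9985e+00	7.0679e-06
7.3407e+00	4.7302e-06
7.6995e+00	3.1020e-06
8.0759e+00	1.9899e-06
8.4707e+00	1.2457e-06
8.8848e+00	7.5843e-07
9.3192e+00	4.4695e-07
9.7747e+00	2.5336e-07
1.0253e+01	1.3711e-07
1.0754e+01	7.0226e-08
1.1280e+01	3.3723e-08
1.1831e+01	1.5034e-08
1.2409e+01	6.1578e-09
1.3016e+01	2.2930e-09
1.3652e+01	7.6770e-10
1.4320e+01	2.2843e-10
1.5020e+01	5.9664e-11
1.5754e+01	1.3498e-11
1.6524e+01	2.6071e-12
1.7332e+01	4.2321e-13
1.8179e+01	5.6764e-14
1.9068e+01	6.1799e-15
2.0000e+01	5.3668e-16
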