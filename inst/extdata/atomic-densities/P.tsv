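# element	P
# Z	15
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-340.717771
r_bohr	rho_e_bohr3
1.5000e-03	2.0924e+03
1.5733e-03	2.0877e+03
1.6502e-03	2.0828e+03
1.7309e-03	2.0776e+03
1.8155e-03	2.0722e+03
1.9043e-03	2.0664e+03
1.9974e-03	2.0603e+03
2.0950e-03	2.0540e+03
2.1974e-03	2.0474e+03
2.3049e-03	2.0405e+03
2.4175e-03	2.0333e+03
2.5357e-03	2.0258e+03
2.6597e-03	2.0181e+03
2.7897e-03	2.0101e+03
2.9261e-03	2.0018e+03
3.0691e-03	1.9932e+03
3.2192e-03	1.9843e+03
3.3765e-03	1.9750e+03
3.5416e-03	1.9654e+03
3.7148e-03	1.9554e+03
3.8964e-03	1.9449e+03
4.0868e-03	1.9340e+03
4.2866e-03	1.9227e+03
4.4962e-03	1.9108e+03
4.7160e-03	1.8983e+03
4.9465e-03	1.8853e+03
5.1883e-03	1.8717e+03
5.4420e-03	1.8575e+03
5.7080e-03	1.8427e+03
5.9871e-03	1.8273e+03
6.2797e-03	1.8112e+03
6.5867e-03	1.7946e+03
6.9087e-03	1.7773e+03
7.2465e-03	1.7593e+03
7.6007e-03	1.7407e+03
7.9723e-03	1.7215e+03
8.3620e-03	1.7015e+03
8.7708e-03	1.6808e+03
9.1996e-03	1.6594e+03
9.6493e-03	1.6373e+03
1.0121e-02	1.6144e+03
1.0616e-02	1.5907e+03
1.1135e-02	1.5662e+03
1.1679e-02	1.5409e+03
1.2250e-02	1.5149e+03
1.2849e-02	1.4880e+03
1.3477e-02	1.4603e+03
1.4136e-02	1.4318e+03
1.4827e-02	1.4025e+03
1.5552e-02	1.3725e+03
1.6312e-02	1.3417e+03
1.7109e-02	1.3101e+03
1.7946e-02	1.2778e+03
1.8823e-02	1.2448e+03
1.9743e-02	1.2111e+03
2.0709e-02	1.1767e+03
2.1721e-02	1.1417e+03
2.2783e-02	1.1062e+03
2.3897e-02	1.0701e+03
2.5065e-02	1.0336e+03
2.6290e-02	9.9659e+02
2.7575e-02	9.5924e+02
2.8923e-02	9.2158e+02
3.0337e-02	8.8370e+02
3.1820e-02	8.4567e+02
3.3376e-02	8.0757e+02
3.5008e-02	7.6948e+02
3.6719e-02	7.3149e+02
3.8514e-02	6.9370e+02
4.0397e-02	6.5621e+02
4.2372e-02	6.1911e+02
4.4443e-02	5.8250e+02
4.6616e-02	5.4649e+02
4.8894e-02	5.1118e+02
5.1285e-02	4.7666e+02
5.3792e-02	4.4304e+02
5.6422e-02	4.1040e+02
5.9180e-02	3.7885e+02
6.2073e-02	3.4846e+02
6.5107e-02	3.1931e+02
6.8290e-02	2.9149e+02
7.1629e-02	2.6505e+02
7.5130e-02	2.4004e+02
7.8803e-02	2.1651e+02
8.2655e-02	1.9450e+02
8.6696e-02	1.7401e+02
9.0934e-02	1.5506e+02
9.5380e-02	1.3764e+02
1.0004e-01	1.2173e+02
1.0493e-01	1.0730e+02
1.1006e-01	9.4311e+01
1.1544e-01	8.2705e+01
1.2109e-01	7.2418e+01
1.2701e-01	6.3373e+01
1.3322e-01	5.5486e+01
1.3973e-01	4.8670e+01
1.4656e-01	4.2829e+01
1.5372e-01	3.7869e+01
1.6124e-01	3.3691e+01
1.6912e-01	3.0198e+01
1.7739e-01	2.7296e+01
1.8606e-01	2.4892e+01
1.9516e-01	2.2901e+01
2.0470e-01	2.1244e+01
2.1470e-01	1.9849e+01
2.2520e-01	1.8652e+01
2.3621e-01	1.7600e+01
2.4776e-01	1.6646e+01
2.5987e-01	1.5754e+01
2.7257e-01	1.4893e+01
2.8590e-01	1.4045e+01
2.9987e-01	1.3193e+01
3.1453e-01	1.2332e+01
3.2991e-01	1.1460e+01
3.4604e-01	1.0580e+01
3.6295e-01	9.6952e+00
3.8070e-01	8.8149e+00
3.9931e-01	7.9470e+00
4.1883e-01	7.1002e+00
4.3930e-01	6.2836e+00
4.6078e-01	5.5057e+00
4.8330e-01	4.7742e+00
5.0693e-01	4.0958e+00
5.3171e-01	3.4758e+00
5.5771e-01	2.9174e+00
5.8497e-01	2.4221e+00
6.1357e-01	1.9893e+00
6.4356e-01	1.6166e+00
6.7502e-01	1.3003e+00
7.0802e-01	1.0360e+00
7.4263e-01	8.1858e-01
7.7894e-01	6.4267e-01
8.1702e-01	5.0301e-01
8.5696e-01	3.9437e-01
8.9885e-01	3.1176e-01
9.4279e-01	2.5040e-01
9.8888e-01	2.0587e-01
1.0372e+00	1.7421e-01
1.0879e+00	1.5197e-01
1.1411e+00	1.3631e-01
1.1969e+00	1.2499e-01
1.2554e+00	1.1633e-01
1.3168e+00	1.0911e-01
1.3812e+00	1.0254e-01
1.4487e+00	9.6103e-02
1.5195e+00	8.9522e-02
1.5938e+00	8.2678e-02
1.6717e+00	7.5574e-02
1.7534e+00	6.8290e-02
1.8391e+00	6.0960e-02
1.9290e+00	5.3734e-02
2.0233e+00	4.6764e-02
2.1223e+00	4.0182e-02
2.2260e+00	3.4092e-02
2.3348e+00	2.8561e-02
2.4490e+00	2.3627e-02
2.5687e+00	1.9298e-02
2.6943e+00	1.5558e-02
2.8260e+00	1.2376e-02
2.9641e+00	9.7087e-03
3.1090e+00	7.5065e-03
3.2610e+00	5.7166e-03
3.4204e+00	4.2859e-03
3.5876e+00	3.1621e-03
3.7630e+00	2.2957e-03
3.9470e+00	1.6403e-03
4.1399e+00	1.1539e-03
4.3423e+00	7.9968e-04
4.5546e+00	5.4609e-04
4.7773e+00	3.6740e-04
5.0108e+00	2.4329e-04
5.2558e+00	1.5825e-04
5.5127e+00	1.0080e-04
5.7822e+00	6.2632e-05
6.0649e+00	3.7792e-05
6.3614e+00	2.2051e-05
6.6723e+00	1.2401e-05
6.9985e+00	6.7101e-06
7.3407e+00	3.4958e-06
7.6995e+00	1.7600e-06
8.0759e+00	8.6222e-07
8.4707e+00	4.1490e-07
8.8848e+00	1.9813e-07
9.3192e+00	9.4650e-08
9.7747e+00	4.5355e-08
1.0253e+01	2.1691e-08
1.0754e+01	1.0226e-08
1.1280e+01	4.6696e-09
1.1831e+01	2.0265e-09
1.2409e+01	8.2077e-10
1.3016e+01	3.0528e-10
1.3652e+01	1.0286e-10
1.4320e+01	3.1028e-11
1.5020e+01	8.3031e-12
1.5754e+01	1.9593e-12
1.6524e+01	4.0783e-13
1.7332e+01	7.5752e-14
1.8179e+01	1.2901e-14
1.9068e+01	2.0904e-15
2.0000e+01	3.2899e-16
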