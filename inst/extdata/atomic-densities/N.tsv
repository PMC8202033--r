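# element	N
# Z	7
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-54.404501
r_bohr	rho_e_bohr3
1.5000e-03	2.0108e+02
1.5733e-03	2.0095e+02
1.6502e-03	2.0081e+02
1.7309e-03	2.0065e+02
1.8155e-03	2.0048e+02
1.9043e-03	2.0030e+02
1.9974e-03	2.0010e+02
2.0950e-03	1.9988e+02
2.1974e-03	1.9965e+02
2.3049e-03	1.9939e+02
2.4175e-03	1.9912e+02
2.5357e-03	1.9882e+02
2.6597e-03	1.9851e+02
2.7897e-03	1.9817e+02
2.9261e-03	1.9780e+02
3.0691e-03	1.9742e+02
3.2192e-03	1.9700e+02
3.3765e-03	1.9656e+02
3.5416e-03	1.9610e+02
3.7148e-03	1.9561e+02
3.8964e-03	1.9509e+02
4.0868e-03	1.9454e+02
4.2866e-03	1.9397e+02
4.4962e-03	1.9337e+02
4.7160e-03	1.9275e+02
4.9465e-03	1.9210e+02
5.1883e-03	1.9143e+02
5.4420e-03	1.9073e+02
5.7080e-03	1.9000e+02
5.9871e-03	1.8925e+02
6.2797e-03	1.8847e+02
6.5867e-03	1.8767e+02
6.9087e-03	1.8683e+02
7.2465e-03	1.8596e+02
7.6007e-03	1.8506e+02
7.9723e-03	1.8411e+02
8.3620e-03	1.8313e+02
8.7708e-03	1.8210e+02
9.1996e-03	1.8103e+02
9.6493e-03	1.7991e+02
1.0121e-02	1.7873e+02
1.0616e-02	1.7750e+02
1.1135e-02	1.7621e+02
1.1679e-02	1.7487e+02
1.2250e-02	1.7348e+02
1.2849e-02	1.7202e+02
1.3477e-02	1.7051e+02
1.4136e-02	1.6894e+02
1.4827e-02	1.6732e+02
1.5552e-02	1.6563e+02
1.6312e-02	1.6388e+02
1.7109e-02	1.6207e+02
1.7946e-02	1.6020e+02
1.8823e-02	1.5825e+02
1.9743e-02	1.5624e+02
2.0709e-02	1.5416e+02
2.1721e-02	1.5200e+02
2.2783e-02	1.4977e+02
2.3897e-02	1.4747e+02
2.5065e-02	1.4509e+02
2.6290e-02	1.4263e+02
2.7575e-02	1.4010e+02
2.8923e-02	1.3750e+02
3.0337e-02	1.3482e+02
3.1820e-02	1.3206e+02
3.3376e-02	1.2924e+02
3.5008e-02	1.2634e+02
3.6719e-02	1.2338e+02
3.8514e-02	1.2034e+02
4.0397e-02	1.1724e+02
4.2372e-02	1.1407e+02
4.4443e-02	1.1085e+02
4.6616e-02	1.0756e+02
4.8894e-02	1.0422e+02
5.1285e-02	1.0083e+02
5.3792e-02	9.7394e+01
5.6422e-02	9.3918e+01
5.9180e-02	9.0407e+01
6.2073e-02	8.6868e+01
6.5107e-02	8.3308e+01
6.8290e-02	7.9732e+01
7.1629e-02	7.6150e+01
7.5130e-02	7.2568e+01
7.8803e-02	6.8996e+01
8.2655e-02	6.5441e+01
8.6696e-02	6.1912e+01
9.0934e-02	5.8419e+01
9.5380e-02	5.4971e+01
1.0004e-01	5.1576e+01
1.0493e-01	4.8244e+01
1.1006e-01	4.4984e+01
1.1544e-01	4.1806e+01
1.2109e-01	3.8718e+01
1.2701e-01	3.5728e+01
1.3322e-01	3.2844e+01
1.3973e-01	3.0074e+01
1.4656e-01	2.7424e+01
1.5372e-01	2.4901e+01
1.6124e-01	2.2508e+01
1.6912e-01	2.0251e+01
1.7739e-01	1.8133e+01
1.8606e-01	1.6155e+01
1.9516e-01	1.4318e+01
2.0470e-01	1.2623e+01
2.1470e-01	1.1068e+01
2.2520e-01	9.6510e+00
2.3621e-01	8.3681e+00
2.4776e-01	7.2150e+00
2.5987e-01	6.1867e+00
2.7257e-01	5.2768e+00
2.8590e-01	4.4784e+00
2.9987e-01	3.7842e+00
3.1453e-01	3.1861e+00
3.2991e-01	2.6759e+00
3.4604e-01	2.2452e+00
3.6295e-01	1.8856e+00
3.8070e-01	1.5889e+00
3.9931e-01	1.3468e+00
4.1883e-01	1.1517e+00
4.3930e-01	9.9641e-01
4.6078e-01	8.7404e-01
4.8330e-01	7.7852e-01
5.0693e-01	7.0438e-01
5.3171e-01	6.4683e-01
5.5771e-01	6.0175e-01
5.8497e-01	5.6565e-01
6.1357e-01	5.3568e-01
6.4356e-01	5.0958e-01
6.7502e-01	4.8558e-01
7.0802e-01	4.6242e-01
7.4263e-01	4.3922e-01
7.7894e-01	4.1546e-01
8.1702e-01	3.9090e-01
8.5696e-01	3.6550e-01
8.9885e-01	3.3938e-01
9.4279e-01	3.1277e-01
9.8888e-01	2.8597e-01
1.0372e+00	2.5933e-01
1.0879e+00	2.3319e-01
1.1411e+00	2.0787e-01
1.1969e+00	1.8366e-01
1.2554e+00	1.6083e-01
1.3168e+00	1.3955e-01
1.3812e+00	1.1997e-01
1.4487e+00	1.0217e-01
1.5195e+00	8.6172e-02
1.5938e+00	7.1968e-02
1.6717e+00	5.9503e-02
1.7534e+00	4.8693e-02
1.8391e+00	3.9431e-02
1.9290e+00	3.1592e-02
2.0233e+00	2.5038e-02
2.1223e+00	1.9625e-02
2.2260e+00	1.5208e-02
2.3348e+00	1.1648e-02
2.4490e+00	8.8134e-03
2.5687e+00	6.5840e-03
2.6943e+00	4.8535e-03
2.8260e+00	3.5287e-03
2.9641e+00	2.5291e-03
3.1090e+00	1.7864e-03
3.2610e+00	1.2432e-03
3.4204e+00	8.5217e-04
3.5876e+00	5.7503e-04
3.7630e+00	3.8167e-04
3.9470e+00	2.4888e-04
4.1399e+00	1.5920e-04
4.3423e+00	9.9724e-05
4.5546e+00	6.1087e-05
4.7773e+00	3.6556e-05
5.0108e+00	2.1367e-05
5.2558e+00	1.2205e-05
5.5127e+00	6.8204e-06
5.7822e+00	3.7323e-06
6.0649e+00	2.0001e-06
6.3614e+00	1.0478e-06
6.6723e+00	5.3435e-07
6.9985e+00	2.6352e-07
7.3407e+00	1.2458e-07
7.6995e+00	5.5912e-08
8.0759e+00	2.3590e-08
8.4707e+00	9.2810e-09
8.8848e+00	3.3884e-09
9.3192e+00	1.1489e-09
9.7747e+00	3.6544e-10
1.0253e+01	1.1162e-10
1.0754e+01	3.4042e-11
1.1280e+01	1.0851e-11
1.1831e+01	3.7272e-12
1.2409e+01	1.3752e-12
1.3016e+01	5.2914e-13
1.3652e+01	2.0501e-13
1.4320e+01	7.7737e-14
1.5020e+01	2.8259e-14
1.5754e+01	9.6872e-15
1.6524e+01	3.0832e-15
1.7332e+01	8.9653e-16
1.8179e+01	2.3422e-16
1.9068e+01	5.4054e-17
2.0000e+01	1.0835e-17
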