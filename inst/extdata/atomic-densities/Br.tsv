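# element	Br
# Z	35
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-2571.896794
r_bohr	rho_e_bohr3
1.5000e-03	2.6618e+04
1.5733e-03	2.6484e+04
1.6502e-03	2.6344e+04
1.7309e-03	2.6198e+04
1.8155e-03	2.6045e+04
1.9043e-03	2.5886e+04
1.9974e-03	2.5720e+04
2.0950e-03	2.5546e+04
2.1974e-03	2.5364e+04
2.3049e-03	2.5175e+04
2.4175e-03	2.4977e+04
2.5357e-03	2.4771e+04
2.6597e-03	2.4556e+04
2.7897e-03	2.4333e+04
2.9261e-03	2.4101e+04
3.0691e-03	2.3860e+04
3.2192e-03	2.3610e+04
3.3765e-03	2.3351e+04
3.5416e-03	2.3083e+04
3.7148e-03	2.2805e+04
3.8964e-03	2.2517e+04
4.0868e-03	2.2220e+04
4.2866e-03	2.1912e+04
4.4962e-03	2.1594e+04
4.7160e-03	2.1265e+04
4.9465e-03	2.0926e+04
5.1883e-03	2.0575e+04
5.4420e-03	2.0214e+04
5.7080e-03	1.9843e+04
5.9871e-03	1.9460e+04
6.2797e-03	1.9066e+04
6.5867e-03	1.8662e+04
6.9087e-03	1.8247e+04
7.2465e-03	1.7822e+04
7.6007e-03	1.7387e+04
7.9723e-03	1.6942e+04
8.3620e-03	1.6488e+04
8.7708e-03	1.6025e+04
9.1996e-03	1.5554e+04
9.6493e-03	1.5074e+04
1.0121e-02	1.4587e+04
1.0616e-02	1.4094e+04
1.1135e-02	1.3595e+04
1.1679e-02	1.3091e+04
1.2250e-02	1.2582e+04
1.2849e-02	1.2071e+04
1.3477e-02	1.1557e+04
1.4136e-02	1.1042e+04
1.4827e-02	1.0527e+04
1.5552e-02	1.0013e+04
1.6312e-02	9.5023e+03
1.7109e-02	8.9951e+03
1.7946e-02	8.4932e+03
1.8823e-02	7.9979e+03
1.9743e-02	7.5105e+03
2.0709e-02	7.0324e+03
2.1721e-02	6.5651e+03
2.2783e-02	6.1100e+03
2.3897e-02	5.6683e+03
2.5065e-02	5.2415e+03
2.6290e-02	4.8307e+03
2.7575e-02	4.4369e+03
2.8923e-02	4.0612e+03
3.0337e-02	3.7044e+03
3.1820e-02	3.3672e+03
3.3376e-02	3.0502e+03
3.5008e-02	2.7539e+03
3.6719e-02	2.4786e+03
3.8514e-02	2.2243e+03
4.0397e-02	1.9909e+03
4.2372e-02	1.7783e+03
4.4443e-02	1.5858e+03
4.6616e-02	1.4129e+03
4.8894e-02	1.2585e+03
5.1285e-02	1.1219e+03
5.3792e-02	1.0018e+03
5.6422e-02	8.9709e+02
5.9180e-02	8.0644e+02
6.2073e-02	7.2853e+02
6.5107e-02	6.6196e+02
6.8290e-02	6.0532e+02
7.1629e-02	5.5719e+02
7.5130e-02	5.1621e+02
7.8803e-02	4.8106e+02
8.2655e-02	4.5054e+02
8.6696e-02	4.2354e+02
9.0934e-02	3.9911e+02
9.5380e-02	3.7644e+02
1.0004e-01	3.5485e+02
1.0493e-01	3.3384e+02
1.1006e-01	3.1306e+02
1.1544e-01	2.9228e+02
1.2109e-01	2.7141e+02
1.2701e-01	2.5045e+02
1.3322e-01	2.2949e+02
1.3973e-01	2.0868e+02
1.4656e-01	1.8821e+02
1.5372e-01	1.6827e+02
1.6124e-01	1.4911e+02
1.6912e-01	1.3095e+02
1.7739e-01	1.1400e+02
1.8606e-01	9.8467e+01
1.9516e-01	8.4497e+01
2.0470e-01	7.2181e+01
2.1470e-01	6.1546e+01
2.2520e-01	5.2548e+01
2.3621e-01	4.5084e+01
2.4776e-01	3.9002e+01
2.5987e-01	3.4127e+01
2.7257e-01	3.0270e+01
2.8590e-01	2.7246e+01
2.9987e-01	2.4883e+01
3.1453e-01	2.3026e+01
3.2991e-01	2.1535e+01
3.4604e-01	2.0287e+01
3.6295e-01	1.9176e+01
3.8070e-01	1.8110e+01
3.9931e-01	1.7021e+01
4.1883e-01	1.5864e+01
4.3930e-01	1.4619e+01
4.6078e-01	1.3292e+01
4.8330e-01	1.1909e+01
5.0693e-01	1.0509e+01
5.3171e-01	9.1379e+00
5.5771e-01	7.8364e+00
5.8497e-01	6.6373e+00
6.1357e-01	5.5618e+00
6.4356e-01	4.6187e+00
6.7502e-01	3.8065e+00
7.0802e-01	3.1163e+00
7.4263e-01	2.5351e+00
7.7894e-01	2.0485e+00
8.1702e-01	1.6430e+00
8.5696e-01	1.3072e+00
8.9885e-01	1.0319e+00
9.4279e-01	8.0994e-01
9.8888e-01	6.3496e-01
1.0372e+00	5.0087e-01
1.0879e+00	4.0118e-01
1.1411e+00	3.2906e-01
1.1969e+00	2.7770e-01
1.2554e+00	2.4088e-01
1.3168e+00	2.1344e-01
1.3812e+00	1.9154e-01
1.4487e+00	1.7263e-01
1.5195e+00	1.5522e-01
1.5938e+00	1.3865e-01
1.6717e+00	1.2270e-01
1.7534e+00	1.0746e-01
1.8391e+00	9.3068e-02
1.9290e+00	7.9709e-02
2.0233e+00	6.7504e-02
2.1223e+00	5.6517e-02
2.2260e+00	4.6759e-02
2.3348e+00	3.8202e-02
2.4490e+00	3.0792e-02
2.5687e+00	2.4461e-02
2.6943e+00	1.9133e-02
2.8260e+00	1.4725e-02
2.9641e+00	1.1147e-02
3.1090e+00	8.3000e-03
3.2610e+00	6.0844e-03
3.4204e+00	4.3970e-03
3.5876e+00	3.1384e-03
3.7630e+00	2.2170e-03
3.9470e+00	1.5529e-03
4.1399e+00	1.0798e-03
4.3423e+00	7.4523e-04
4.5546e+00	5.0960e-04
4.7773e+00	3.4412e-04
5.0108e+00	2.2838e-04
5.2558e+00	1.4815e-04
5.5127e+00	9.3414e-05
5.7822e+00	5.6982e-05
6.0649e+00	3.3521e-05
6.3614e+00	1.9005e-05
6.6723e+00	1.0413e-05
6.9985e+00	5.5517e-06
7.3407e+00	2.9120e-06
7.6995e+00	1.5241e-06
8.0759e+00	8.0686e-07
8.4707e+00	4.3562e-07
8.8848e+00	2.3959e-07
9.3192e+00	1.3283e-07
9.7747e+00	7.3021e-08
1.0253e+01	3.9077e-08
1.0754e+01	2.0005e-08
1.1280e+01	9.6476e-09
1.1831e+01	4.3253e-09
1.2409e+01	1.7820e-09
1.3016e+01	6.6757e-10
1.3652e+01	2.2511e-10
1.4320e+01	6.7658e-11
1.5020e+01	1.7958e-11
1.5754e+01	4.1769e-12
1.6524e+01	8.4829e-13
1.7332e+01	1.5122e-13
1.8179e+01	2.4166e-14
1.9068e+01	3.6035e-15
2.0000e+01	5.2207e-16
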