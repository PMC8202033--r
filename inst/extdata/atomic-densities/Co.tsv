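# element	Co
# Z	27
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1380.841499
r_bohr	rho_e_bohr3
1.5000e-03	1.2326e+04
1.5733e-03	1.2276e+04
1.6502e-03	1.2225e+04
1.7309e-03	1.2171e+04
1.8155e-03	1.2116e+04
1.9043e-03	1.2059e+04
1.9974e-03	1.1999e+04
2.0950e-03	1.1937e+04
2.1974e-03	1.1872e+04
2.3049e-03	1.1804e+04
2.4175e-03	1.1734e+04
2.5357e-03	1.1660e+04
2.6597e-03	1.1583e+04
2.7897e-03	1.1502e+04
2.9261e-03	1.1418e+04
3.0691e-03	1.1330e+04
3.2192e-03	1.1239e+04
3.3765e-03	1.1143e+04
3.5416e-03	1.1044e+04
3.7148e-03	1.0941e+04
3.8964e-03	1.0834e+04
4.0868e-03	1.0723e+04
4.2866e-03	1.0608e+04
4.4962e-03	1.0488e+04
4.7160e-03	1.0364e+04
4.9465e-03	1.0236e+04
5.1883e-03	1.0104e+04
5.4420e-03	9.9669e+03
5.7080e-03	9.8252e+03
5.9871e-03	9.6787e+03
6.2797e-03	9.5275e+03
6.5867e-03	9.3714e+03
6.9087e-03	9.2103e+03
7.2465e-03	9.0444e+03
7.6007e-03	8.8736e+03
7.9723e-03	8.6978e+03
8.3620e-03	8.5172e+03
8.7708e-03	8.3319e+03
9.1996e-03	8.1418e+03
9.6493e-03	7.9471e+03
1.0121e-02	7.7479e+03
1.0616e-02	7.5445e+03
1.1135e-02	7.3369e+03
1.1679e-02	7.1254e+03
1.2250e-02	6.9103e+03
1.2849e-02	6.6917e+03
1.3477e-02	6.4700e+03
1.4136e-02	6.2455e+03
1.4827e-02	6.0185e+03
1.5552e-02	5.7894e+03
1.6312e-02	5.5587e+03
1.7109e-02	5.3268e+03
1.7946e-02	5.0941e+03
1.8823e-02	4.8612e+03
1.9743e-02	4.6286e+03
2.0709e-02	4.3970e+03
2.1721e-02	4.1668e+03
2.2783e-02	3.9386e+03
2.3897e-02	3.7131e+03
2.5065e-02	3.4909e+03
2.6290e-02	3.2725e+03
2.7575e-02	3.0588e+03
2.8923e-02	2.8502e+03
3.0337e-02	2.6475e+03
3.1820e-02	2.4511e+03
3.3376e-02	2.2617e+03
3.5008e-02	2.0797e+03
3.6719e-02	1.9057e+03
3.8514e-02	1.7399e+03
4.0397e-02	1.5829e+03
4.2372e-02	1.4349e+03
4.4443e-02	1.2961e+03
4.6616e-02	1.1667e+03
4.8894e-02	1.0468e+03
5.1285e-02	9.3645e+02
5.3792e-02	8.3545e+02
5.6422e-02	7.4365e+02
5.9180e-02	6.6080e+02
6.2073e-02	5.8658e+02
6.5107e-02	5.2058e+02
6.8290e-02	4.6237e+02
7.1629e-02	4.1143e+02
7.5130e-02	3.6721e+02
7.8803e-02	3.2913e+02
8.2655e-02	2.9655e+02
8.6696e-02	2.6885e+02
9.0934e-02	2.4539e+02
9.5380e-02	2.2554e+02
1.0004e-01	2.0871e+02
1.0493e-01	1.9433e+02
1.1006e-01	1.8189e+02
1.1544e-01	1.7092e+02
1.2109e-01	1.6103e+02
1.2701e-01	1.5187e+02
1.3322e-01	1.4317e+02
1.3973e-01	1.3470e+02
1.4656e-01	1.2633e+02
1.5372e-01	1.1795e+02
1.6124e-01	1.0952e+02
1.6912e-01	1.0102e+02
1.7739e-01	9.2490e+01
1.8606e-01	8.3982e+01
1.9516e-01	7.5574e+01
2.0470e-01	6.7363e+01
2.1470e-01	5.9453e+01
2.2520e-01	5.1949e+01
2.3621e-01	4.4946e+01
2.4776e-01	3.8520e+01
2.5987e-01	3.2727e+01
2.7257e-01	2.7592e+01
2.8590e-01	2.3120e+01
2.9987e-01	1.9290e+01
3.1453e-01	1.6068e+01
3.2991e-01	1.3407e+01
3.4604e-01	1.1252e+01
3.6295e-01	9.5438e+00
3.8070e-01	8.2198e+00
3.9931e-01	7.2155e+00
4.1883e-01	6.4665e+00
4.3930e-01	5.9105e+00
4.6078e-01	5.4907e+00
4.8330e-01	5.1581e+00
5.0693e-01	4.8741e+00
5.3171e-01	4.6103e+00
5.5771e-01	4.3486e+00
5.8497e-01	4.0794e+00
6.1357e-01	3.7990e+00
6.4356e-01	3.5075e+00
6.7502e-01	3.2073e+00
7.0802e-01	2.9021e+00
7.4263e-01	2.5956e+00
7.7894e-01	2.2923e+00
8.1702e-01	1.9967e+00
8.5696e-01	1.7137e+00
8.9885e-01	1.4483e+00
9.4279e-01	1.2050e+00
9.8888e-01	9.8749e-01
1.0372e+00	7.9806e-01
1.0879e+00	6.3738e-01
1.1411e+00	5.0454e-01
1.1969e+00	3.9724e-01
1.2554e+00	3.1226e-01
1.3168e+00	2.4591e-01
1.3812e+00	1.9449e-01
1.4487e+00	1.5463e-01
1.5195e+00	1.2350e-01
1.5938e+00	9.8918e-02
1.6717e+00	7.9287e-02
1.7534e+00	6.3522e-02
1.8391e+00	5.0882e-02
1.9290e+00	4.0833e-02
2.0233e+00	3.2940e-02
2.1223e+00	2.6810e-02
2.2260e+00	2.2071e-02
2.3348e+00	1.8388e-02
2.4490e+00	1.5475e-02
2.5687e+00	1.3108e-02
2.6943e+00	1.1126e-02
2.8260e+00	9.4196e-03
2.9641e+00	7.9242e-03
3.1090e+00	6.6035e-03
3.2610e+00	5.4392e-03
3.4204e+00	4.4228e-03
3.5876e+00	3.5482e-03
3.7630e+00	2.8086e-03
3.9470e+00	2.1941e-03
4.1399e+00	1.6924e-03
4.3423e+00	1.2892e-03
4.5546e+00	9.6983e-04
4.7773e+00	7.2022e-04
5.0108e+00	5.2759e-04
5.2558e+00	3.8078e-04
5.5127e+00	2.7031e-04
5.7822e+00	1.8834e-04
6.0649e+00	1.2846e-04
6.3614e+00	8.5536e-05
6.6723e+00	5.5437e-05
6.9985e+00	3.4883e-05
7.3407e+00	2.1268e-05
7.6995e+00	1.2550e-05
8.0759e+00	7.1681e-06
8.4707e+00	3.9691e-06
8.8848e+00	2.1370e-06
9.3192e+00	1.1236e-06
9.7747e+00	5.7976e-07
1.0253e+01	2.9502e-07
1.0754e+01	1.4856e-07
1.1280e+01	7.4080e-08
1.1831e+01	3.6481e-08
1.2409e+01	1.7625e-08
1.3016e+01	8.2692e-09
1.3652e+01	3.7215e-09
1.4320e+01	1.5849e-09
1.5020e+01	6.3007e-10
1.5754e+01	2.3078e-10
1.6524e+01	7.6905e-11
1.7332e+01	2.3031e-11
1.8179e+01	6.1224e-12
1.9068e+01	1.4263e-12
2.0000e+01	2.8725e-13
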