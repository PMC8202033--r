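# element	Ar
# Z	18
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-526.813056
r_bohr	rho_e_bohr3
1.5000e-03	3.6412e+03
1.5733e-03	3.6311e+03
1.6502e-03	3.6206e+03
1.7309e-03	3.6095e+03
1.8155e-03	3.5980e+03
1.9043e-03	3.5859e+03
1.9974e-03	3.5734e+03
2.0950e-03	3.5604e+03
2.1974e-03	3.5469e+03
2.3049e-03	3.5329e+03
2.4175e-03	3.5184e+03
2.5357e-03	3.5034e+03
2.6597e-03	3.4878e+03
2.7897e-03	3.4716e+03
2.9261e-03	3.4549e+03
3.0691e-03	3.4374e+03
3.2192e-03	3.4192e+03
3.3765e-03	3.4002e+03
3.5416e-03	3.3803e+03
3.7148e-03	3.3596e+03
3.8964e-03	3.3379e+03
4.0868e-03	3.3153e+03
4.2866e-03	3.2916e+03
4.4962e-03	3.2668e+03
4.7160e-03	3.2411e+03
4.9465e-03	3.2142e+03
5.1883e-03	3.1862e+03
5.4420e-03	3.1572e+03
5.7080e-03	3.1270e+03
5.9871e-03	3.0956e+03
6.2797e-03	3.0632e+03
6.5867e-03	3.0295e+03
6.9087e-03	2.9946e+03
7.2465e-03	2.9585e+03
7.6007e-03	2.9212e+03
7.9723e-03	2.8825e+03
8.3620e-03	2.8425e+03
8.7708e-03	2.8011e+03
9.1996e-03	2.7584e+03
9.6493e-03	2.7143e+03
1.0121e-02	2.6687e+03
1.0616e-02	2.6218e+03
1.1135e-02	2.5734e+03
1.1679e-02	2.5236e+03
1.2250e-02	2.4725e+03
1.2849e-02	2.4199e+03
1.3477e-02	2.3660e+03
1.4136e-02	2.3107e+03
1.4827e-02	2.2542e+03
1.5552e-02	2.1964e+03
1.6312e-02	2.1374e+03
1.7109e-02	2.0773e+03
1.7946e-02	2.0160e+03
1.8823e-02	1.9538e+03
1.9743e-02	1.8906e+03
2.0709e-02	1.8265e+03
2.1721e-02	1.7617e+03
2.2783e-02	1.6962e+03
2.3897e-02	1.6301e+03
2.5065e-02	1.5637e+03
2.6290e-02	1.4969e+03
2.7575e-02	1.4300e+03
2.8923e-02	1.3632e+03
3.0337e-02	1.2964e+03
3.1820e-02	1.2300e+03
3.3376e-02	1.1641e+03
3.5008e-02	1.0988e+03
3.6719e-02	1.0344e+03
3.8514e-02	9.7104e+02
4.0397e-02	9.0885e+02
4.2372e-02	8.4805e+02
4.4443e-02	7.8881e+02
4.6616e-02	7.3128e+02
4.8894e-02	6.7564e+02
5.1285e-02	6.2204e+02
5.3792e-02	5.7061e+02
5.6422e-02	5.2149e+02
5.9180e-02	4.7479e+02
6.2073e-02	4.3062e+02
6.5107e-02	3.8905e+02
6.8290e-02	3.5014e+02
7.1629e-02	3.1392e+02
7.5130e-02	2.8041e+02
7.8803e-02	2.4959e+02
8.2655e-02	2.2144e+02
8.6696e-02	1.9589e+02
9.0934e-02	1.7289e+02
9.5380e-02	1.5233e+02
1.0004e-01	1.3410e+02
1.0493e-01	1.1806e+02
1.1006e-01	1.0407e+02
1.1544e-01	9.1972e+01
1.2109e-01	8.1587e+01
1.2701e-01	7.2747e+01
1.3322e-01	6.5276e+01
1.3973e-01	5.9001e+01
1.4656e-01	5.3753e+01
1.5372e-01	4.9367e+01
1.6124e-01	4.5691e+01
1.6912e-01	4.2583e+01
1.7739e-01	3.9916e+01
1.8606e-01	3.7576e+01
1.9516e-01	3.5470e+01
2.0470e-01	3.3517e+01
2.1470e-01	3.1653e+01
2.2520e-01	2.9831e+01
2.3621e-01	2.8016e+01
2.4776e-01	2.6187e+01
2.5987e-01	2.4336e+01
2.7257e-01	2.2463e+01
2.8590e-01	2.0580e+01
2.9987e-01	1.8701e+01
3.1453e-01	1.6846e+01
3.2991e-01	1.5037e+01
3.4604e-01	1.3292e+01
3.6295e-01	1.1631e+01
3.8070e-01	1.0070e+01
3.9931e-01	8.6210e+00
4.1883e-01	7.2962e+00
4.3930e-01	6.1030e+00
4.6078e-01	5.0460e+00
4.8330e-01	4.1262e+00
5.0693e-01	3.3406e+00
5.3171e-01	2.6826e+00
5.5771e-01	2.1426e+00
5.8497e-01	1.7082e+00
6.1357e-01	1.3659e+00
6.4356e-01	1.1019e+00
6.7502e-01	9.0251e-01
7.0802e-01	7.5528e-01
7.4263e-01	6.4900e-01
7.7894e-01	5.7383e-01
8.1702e-01	5.2129e-01
8.5696e-01	4.8424e-01
8.9885e-01	4.5679e-01
9.4279e-01	4.3436e-01
9.8888e-01	4.1360e-01
1.0372e+00	3.9235e-01
1.0879e+00	3.6943e-01
1.1411e+00	3.4448e-01
1.1969e+00	3.1768e-01
1.2554e+00	2.8953e-01
1.3168e+00	2.6070e-01
1.3812e+00	2.3186e-01
1.4487e+00	2.0365e-01
1.5195e+00	1.7659e-01
1.5938e+00	1.5114e-01
1.6717e+00	1.2763e-01
1.7534e+00	1.0631e-01
1.8391e+00	8.7320e-02
1.9290e+00	7.0720e-02
2.0233e+00	5.6477e-02
2.1223e+00	4.4487e-02
2.2260e+00	3.4579e-02
2.3348e+00	2.6538e-02
2.4490e+00	2.0122e-02
2.5687e+00	1.5081e-02
2.6943e+00	1.1174e-02
2.8260e+00	8.1819e-03
2.9641e+00	5.9147e-03
3.1090e+00	4.2149e-03
3.2610e+00	2.9550e-03
3.4204e+00	2.0339e-03
3.5876e+00	1.3719e-03
3.7630e+00	9.0583e-04
3.9470e+00	5.8535e-04
4.1399e+00	3.7058e-04
4.3423e+00	2.3034e-04
4.5546e+00	1.4094e-04
4.7773e+00	8.5109e-05
5.0108e+00	5.0778e-05
5.2558e+00	2.9895e-05
5.5127e+00	1.7291e-05
5.7822e+00	9.7490e-06
6.0649e+00	5.3015e-06
6.3614e+00	2.7446e-06
6.6723e+00	1.3326e-06
6.9985e+00	5.9660e-07
7.3407e+00	2.4119e-07
7.6995e+00	8.5587e-08
8.0759e+00	2.5477e-08
8.4707e+00	5.8325e-09
8.8848e+00	8.4402e-10
9.3192e+00	9.2081e-11
9.7747e+00	1.4167e-10
1.0253e+01	1.8044e-10
1.0754e+01	1.4520e-10
1.1280e+01	9.0782e-11
1.1831e+01	4.8305e-11
1.2409e+01	2.2880e-11
1.3016e+01	9.8864e-12
1.3652e+01	3.9532e-12
1.4320e+01	1.4757e-12
1.5020e+01	5.1677e-13
1.5754e+01	1.6978e-13
1.6524e+01	5.2044e-14
1.7332e+01	1.4711e-14
1.8179e+01	3.7722e-15
1.9068e+01	8.6109e-16
2.0000e+01	1.7162e-16
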