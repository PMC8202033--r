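# element	Al
# Z	13
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-241.802333
r_bohr	rho_e_bohr3
1.5000e-03	1.3506e+03
1.5733e-03	1.3482e+03
1.6502e-03	1.3456e+03
1.7309e-03	1.3428e+03
1.8155e-03	1.3398e+03
1.9043e-03	1.3366e+03
1.9974e-03	1.3333e+03
2.0950e-03	1.3298e+03
2.1974e-03	1.3261e+03
2.3049e-03	1.3222e+03
2.4175e-03	1.3181e+03
2.5357e-03	1.3139e+03
2.6597e-03	1.3094e+03
2.7897e-03	1.3048e+03
2.9261e-03	1.3000e+03
3.0691e-03	1.2951e+03
3.2192e-03	1.2900e+03
3.3765e-03	1.2846e+03
3.5416e-03	1.2791e+03
3.7148e-03	1.2734e+03
3.8964e-03	1.2675e+03
4.0868e-03	1.2613e+03
4.2866e-03	1.2549e+03
4.4962e-03	1.2482e+03
4.7160e-03	1.2412e+03
4.9465e-03	1.2339e+03
5.1883e-03	1.2262e+03
5.4420e-03	1.2182e+03
5.7080e-03	1.2099e+03
5.9871e-03	1.2011e+03
6.2797e-03	1.1920e+03
6.5867e-03	1.1825e+03
6.9087e-03	1.1726e+03
7.2465e-03	1.1623e+03
7.6007e-03	1.1517e+03
7.9723e-03	1.1406e+03
8.3620e-03	1.1290e+03
8.7708e-03	1.1171e+03
9.1996e-03	1.1047e+03
9.6493e-03	1.0919e+03
1.0121e-02	1.0787e+03
1.0616e-02	1.0649e+03
1.1135e-02	1.0507e+03
1.1679e-02	1.0360e+03
1.2250e-02	1.0208e+03
1.2849e-02	1.0051e+03
1.3477e-02	9.8893e+02
1.4136e-02	9.7220e+02
1.4827e-02	9.5495e+02
1.5552e-02	9.3718e+02
1.6312e-02	9.1891e+02
1.7109e-02	9.0012e+02
1.7946e-02	8.8084e+02
1.8823e-02	8.6106e+02
1.9743e-02	8.4080e+02
2.0709e-02	8.2008e+02
2.1721e-02	7.9889e+02
2.2783e-02	7.7728e+02
2.3897e-02	7.5524e+02
2.5065e-02	7.3281e+02
2.6290e-02	7.1001e+02
2.7575e-02	6.8687e+02
2.8923e-02	6.6341e+02
3.0337e-02	6.3968e+02
3.1820e-02	6.1572e+02
3.3376e-02	5.9156e+02
3.5008e-02	5.6725e+02
3.6719e-02	5.4285e+02
3.8514e-02	5.1839e+02
4.0397e-02	4.9395e+02
4.2372e-02	4.6957e+02
4.4443e-02	4.4532e+02
4.6616e-02	4.2125e+02
4.8894e-02	3.9744e+02
5.1285e-02	3.7394e+02
5.3792e-02	3.5081e+02
5.6422e-02	3.2814e+02
5.9180e-02	3.0597e+02
6.2073e-02	2.8436e+02
6.5107e-02	2.6339e+02
6.8290e-02	2.4311e+02
7.1629e-02	2.2357e+02
7.5130e-02	2.0482e+02
7.8803e-02	1.8692e+02
8.2655e-02	1.6990e+02
8.6696e-02	1.5380e+02
9.0934e-02	1.3864e+02
9.5380e-02	1.2445e+02
1.0004e-01	1.1123e+02
1.0493e-01	9.8995e+01
1.1006e-01	8.7741e+01
1.1544e-01	7.7455e+01
1.2109e-01	6.8120e+01
1.2701e-01	5.9707e+01
1.3322e-01	5.2182e+01
1.3973e-01	4.5504e+01
1.4656e-01	3.9626e+01
1.5372e-01	3.4495e+01
1.6124e-01	3.0057e+01
1.6912e-01	2.6253e+01
1.7739e-01	2.3021e+01
1.8606e-01	2.0301e+01
1.9516e-01	1.8031e+01
2.0470e-01	1.6150e+01
2.1470e-01	1.4601e+01
2.2520e-01	1.3328e+01
2.3621e-01	1.2281e+01
2.4776e-01	1.1415e+01
2.5987e-01	1.0687e+01
2.7257e-01	1.0064e+01
2.8590e-01	9.5134e+00
2.9987e-01	9.0112e+00
3.1453e-01	8.5373e+00
3.2991e-01	8.0770e+00
3.4604e-01	7.6199e+00
3.6295e-01	7.1598e+00
3.8070e-01	6.6936e+00
3.9931e-01	6.2209e+00
4.1883e-01	5.7435e+00
4.3930e-01	5.2642e+00
4.6078e-01	4.7874e+00
4.8330e-01	4.3176e+00
5.0693e-01	3.8600e+00
5.3171e-01	3.4196e+00
5.5771e-01	3.0013e+00
5.8497e-01	2.6090e+00
6.1357e-01	2.2460e+00
6.4356e-01	1.9144e+00
6.7502e-01	1.6154e+00
7.0802e-01	1.3490e+00
7.4263e-01	1.1147e+00
7.7894e-01	9.1106e-01
8.1702e-01	7.3643e-01
8.5696e-01	5.8875e-01
8.9885e-01	4.6571e-01
9.4279e-01	3.6484e-01
9.8888e-01	2.8353e-01
1.0372e+00	2.1912e-01
1.0879e+00	1.6897e-01
1.1411e+00	1.3057e-01
1.1969e+00	1.0163e-01
1.2554e+00	8.0133e-02
1.3168e+00	6.4366e-02
1.3812e+00	5.2919e-02
1.4487e+00	4.4657e-02
1.5195e+00	3.8684e-02
1.5938e+00	3.4304e-02
1.6717e+00	3.0983e-02
1.7534e+00	2.8325e-02
1.8391e+00	2.6048e-02
1.9290e+00	2.3967e-02
2.0233e+00	2.1972e-02
2.1223e+00	2.0009e-02
2.2260e+00	1.8063e-02
2.3348e+00	1.6143e-02
2.4490e+00	1.4272e-02
2.5687e+00	1.2477e-02
2.6943e+00	1.0784e-02
2.8260e+00	9.2149e-03
2.9641e+00	7.7861e-03
3.1090e+00	6.5073e-03
3.2610e+00	5.3816e-03
3.4204e+00	4.4063e-03
3.5876e+00	3.5740e-03
3.7630e+00	2.8739e-03
3.9470e+00	2.2927e-03
4.1399e+00	1.8160e-03
4.3423e+00	1.4294e-03
4.5546e+00	1.1188e-03
4.7773e+00	8.7122e-04
5.0108e+00	6.7517e-04
5.2558e+00	5.2064e-04
5.5127e+00	3.9924e-04
5.7822e+00	3.0412e-04
6.0649e+00	2.2978e-04
6.3614e+00	1.7188e-04
6.6723e+00	1.2700e-04
6.9985e+00	9.2461e-05
7.3407e+00	6.6135e-05
7.6995e+00	4.6319e-05
8.0759e+00	3.1639e-05
8.4707e+00	2.0981e-05
8.8848e+00	1.3435e-05
9.3192e+00	8.2587e-06
9.7747e+00	4.8410e-06
1.0253e+01	2.6867e-06
1.0754e+01	1.4011e-06
1.1280e+01	6.8105e-07
1.1831e+01	3.0599e-07
1.2409e+01	1.2595e-07
1.3016e+01	4.7045e-08
1.3652e+01	1.5788e-08
1.4320e+01	4.7098e-09
1.5020e+01	1.2347e-09
1.5754e+01	2.8116e-10
1.6524e+01	5.4970e-11
1.7332e+01	9.1409e-12
1.8179e+01	1.2889e-12
1.9068e+01	1.5609e-13
2.0000e+01	1.6947e-14
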