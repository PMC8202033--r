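# element	Ge
# Z	32
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-2075.018016
r_bohr	rho_e_bohr3
1.5000e-03	2.0415e+04
1.5733e-03	2.0320e+04
1.6502e-03	2.0221e+04
1.7309e-03	2.0118e+04
1.8155e-03	2.0011e+04
1.9043e-03	1.9899e+04
1.9974e-03	1.9783e+04
2.0950e-03	1.9661e+04
2.1974e-03	1.9534e+04
2.3049e-03	1.9401e+04
2.4175e-03	1.9263e+04
2.5357e-03	1.9118e+04
2.6597e-03	1.8967e+04
2.7897e-03	1.8809e+04
2.9261e-03	1.8645e+04
3.0691e-03	1.8475e+04
3.2192e-03	1.8298e+04
3.3765e-03	1.8114e+04
3.5416e-03	1.7923e+04
3.7148e-03	1.7725e+04
3.8964e-03	1.7520e+04
4.0868e-03	1.7308e+04
4.2866e-03	1.7089e+04
4.4962e-03	1.6861e+04
4.7160e-03	1.6627e+04
4.9465e-03	1.6384e+04
5.1883e-03	1.6133e+04
5.4420e-03	1.5874e+04
5.7080e-03	1.5607e+04
5.9871e-03	1.5331e+04
6.2797e-03	1.5048e+04
6.5867e-03	1.4756e+04
6.9087e-03	1.4456e+04
7.2465e-03	1.4148e+04
7.6007e-03	1.3831e+04
7.9723e-03	1.3507e+04
8.3620e-03	1.3176e+04
8.7708e-03	1.2837e+04
9.1996e-03	1.2491e+04
9.6493e-03	1.2138e+04
1.0121e-02	1.1779e+04
1.0616e-02	1.1413e+04
1.1135e-02	1.1043e+04
1.1679e-02	1.0667e+04
1.2250e-02	1.0287e+04
1.2849e-02	9.9037e+03
1.3477e-02	9.5169e+03
1.4136e-02	9.1277e+03
1.4827e-02	8.7368e+03
1.5552e-02	8.3453e+03
1.6312e-02	7.9539e+03
1.7109e-02	7.5637e+03
1.7946e-02	7.1754e+03
1.8823e-02	6.7903e+03
1.9743e-02	6.4092e+03
2.0709e-02	6.0332e+03
2.1721e-02	5.6633e+03
2.2783e-02	5.3007e+03
2.3897e-02	4.9464e+03
2.5065e-02	4.6014e+03
2.6290e-02	4.2667e+03
2.7575e-02	3.9434e+03
2.8923e-02	3.6323e+03
3.0337e-02	3.3343e+03
3.1820e-02	3.0501e+03
3.3376e-02	2.7802e+03
3.5008e-02	2.5253e+03
3.6719e-02	2.2858e+03
3.8514e-02	2.0621e+03
4.0397e-02	1.8542e+03
4.2372e-02	1.6624e+03
4.4443e-02	1.4865e+03
4.6616e-02	1.3263e+03
4.8894e-02	1.1813e+03
5.1285e-02	1.0511e+03
5.3792e-02	9.3501e+02
5.6422e-02	8.3227e+02
5.9180e-02	7.4205e+02
6.2073e-02	6.6346e+02
6.5107e-02	5.9552e+02
6.8290e-02	5.3720e+02
7.1629e-02	4.8745e+02
7.5130e-02	4.4518e+02
7.8803e-02	4.0932e+02
8.2655e-02	3.7885e+02
8.6696e-02	3.5278e+02
9.0934e-02	3.3020e+02
9.5380e-02	3.1028e+02
1.0004e-01	2.9232e+02
1.0493e-01	2.7569e+02
1.1006e-01	2.5991e+02
1.1544e-01	2.4458e+02
1.2109e-01	2.2943e+02
1.2701e-01	2.1430e+02
1.3322e-01	1.9909e+02
1.3973e-01	1.8381e+02
1.4656e-01	1.6850e+02
1.5372e-01	1.5327e+02
1.6124e-01	1.3823e+02
1.6912e-01	1.2357e+02
1.7739e-01	1.0943e+02
1.8606e-01	9.6010e+01
1.9516e-01	8.3469e+01
2.0470e-01	7.1957e+01
2.1470e-01	6.1585e+01
2.2520e-01	5.2418e+01
2.3621e-01	4.4474e+01
2.4776e-01	3.7720e+01
2.5987e-01	3.2084e+01
2.7257e-01	2.7464e+01
2.8590e-01	2.3740e+01
2.9987e-01	2.0787e+01
3.1453e-01	1.8478e+01
3.2991e-01	1.6692e+01
3.4604e-01	1.5314e+01
3.6295e-01	1.4239e+01
3.8070e-01	1.3368e+01
3.9931e-01	1.2618e+01
4.1883e-01	1.1916e+01
4.3930e-01	1.1214e+01
4.6078e-01	1.0478e+01
4.8330e-01	9.6973e+00
5.0693e-01	8.8771e+00
5.3171e-01	8.0336e+00
5.5771e-01	7.1883e+00
5.8497e-01	6.3636e+00
6.1357e-01	5.5780e+00
6.4356e-01	4.8448e+00
6.7502e-01	4.1712e+00
7.0802e-01	3.5595e+00
7.4263e-01	3.0088e+00
7.7894e-01	2.5160e+00
8.1702e-01	2.0782e+00
8.5696e-01	1.6926e+00
8.9885e-01	1.3575e+00
9.4279e-01	1.0715e+00
9.8888e-01	8.3286e-01
1.0372e+00	6.3911e-01
1.0879e+00	4.8636e-01
1.1411e+00	3.6950e-01
1.1969e+00	2.8254e-01
1.2554e+00	2.1926e-01
1.3168e+00	1.7381e-01
1.3812e+00	1.4111e-01
1.4487e+00	1.1716e-01
1.5195e+00	9.8992e-02
1.5938e+00	8.4593e-02
1.6717e+00	7.2697e-02
1.7534e+00	6.2573e-02
1.8391e+00	5.3827e-02
1.9290e+00	4.6242e-02
2.0233e+00	3.9670e-02
2.1223e+00	3.3981e-02
2.2260e+00	2.9043e-02
2.3348e+00	2.4736e-02
2.4490e+00	2.0958e-02
2.5687e+00	1.7634e-02
2.6943e+00	1.4713e-02
2.8260e+00	1.2160e-02
2.9641e+00	9.9497e-03
3.1090e+00	8.0581e-03
3.2610e+00	6.4597e-03
3.4204e+00	5.1265e-03
3.5876e+00	4.0285e-03
3.7630e+00	3.1347e-03
3.9470e+00	2.4151e-03
4.1399e+00	1.8415e-03
4.3423e+00	1.3885e-03
4.5546e+00	1.0341e-03
4.7773e+00	7.5949e-04
5.0108e+00	5.4929e-04
5.2558e+00	3.9065e-04
5.5127e+00	2.7295e-04
5.7822e+00	1.8734e-04
6.0649e+00	1.2643e-04
6.3614e+00	8.4045e-05
6.6723e+00	5.5184e-05
6.9985e+00	3.5894e-05
7.3407e+00	2.3183e-05
7.6995e+00	1.4882e-05
8.0759e+00	9.4811e-06
8.4707e+00	5.9694e-06
8.8848e+00	3.6890e-06
9.3192e+00	2.2177e-06
9.7747e+00	1.2839e-06
1.0253e+01	7.0839e-07
1.0754e+01	3.6866e-07
1.1280e+01	1.7917e-07
1.1831e+01	8.0540e-08
1.2409e+01	3.3166e-08
1.3016e+01	1.2390e-08
1.3652e+01	4.1561e-09
1.4320e+01	1.2381e-09
1.5020e+01	3.2366e-10
1.5754e+01	7.3300e-11
1.6524e+01	1.4182e-11
1.7332e+01	2.3095e-12
1.8179e+01	3.1190e-13
1.9068e+01	3.4486e-14
2.0000e+01	3.1088e-15
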