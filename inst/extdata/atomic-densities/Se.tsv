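# element	Se
# Z	34
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-2399.407017
r_bohr	rho_e_bohr3
1.5000e-03	2.4431e+04
1.5733e-03	2.4311e+04
1.6502e-03	2.4186e+04
1.7309e-03	2.4056e+04
1.8155e-03	2.3920e+04
1.9043e-03	2.3778e+04
1.9974e-03	2.3630e+04
2.0950e-03	2.3475e+04
2.1974e-03	2.3313e+04
2.3049e-03	2.3144e+04
2.4175e-03	2.2968e+04
2.5357e-03	2.2784e+04
2.6597e-03	2.2592e+04
2.7897e-03	2.2393e+04
2.9261e-03	2.2185e+04
3.0691e-03	2.1970e+04
3.2192e-03	2.1746e+04
3.3765e-03	2.1514e+04
3.5416e-03	2.1274e+04
3.7148e-03	2.1025e+04
3.8964e-03	2.0767e+04
4.0868e-03	2.0500e+04
4.2866e-03	2.0224e+04
4.4962e-03	1.9939e+04
4.7160e-03	1.9644e+04
4.9465e-03	1.9339e+04
5.1883e-03	1.9025e+04
5.4420e-03	1.8701e+04
5.7080e-03	1.8366e+04
5.9871e-03	1.8022e+04
6.2797e-03	1.7668e+04
6.5867e-03	1.7304e+04
6.9087e-03	1.6930e+04
7.2465e-03	1.6547e+04
7.6007e-03	1.6155e+04
7.9723e-03	1.5753e+04
8.3620e-03	1.5342e+04
8.7708e-03	1.4923e+04
9.1996e-03	1.4497e+04
9.6493e-03	1.4062e+04
1.0121e-02	1.3621e+04
1.0616e-02	1.3173e+04
1.1135e-02	1.2719e+04
1.1679e-02	1.2261e+04
1.2250e-02	1.1798e+04
1.2849e-02	1.1331e+04
1.3477e-02	1.0862e+04
1.4136e-02	1.0391e+04
1.4827e-02	9.9195e+03
1.5552e-02	9.4486e+03
1.6312e-02	8.9794e+03
1.7109e-02	8.5129e+03
1.7946e-02	8.0505e+03
1.8823e-02	7.5934e+03
1.9743e-02	7.1427e+03
2.0709e-02	6.6998e+03
2.1721e-02	6.2660e+03
2.2783e-02	5.8424e+03
2.3897e-02	5.4305e+03
2.5065e-02	5.0314e+03
2.6290e-02	4.6463e+03
2.7575e-02	4.2763e+03
2.8923e-02	3.9222e+03
3.0337e-02	3.5849e+03
3.1820e-02	3.2652e+03
3.3376e-02	2.9636e+03
3.5008e-02	2.6807e+03
3.6719e-02	2.4169e+03
3.8514e-02	2.1723e+03
4.0397e-02	1.9469e+03
4.2372e-02	1.7407e+03
4.4443e-02	1.5532e+03
4.6616e-02	1.3840e+03
4.8894e-02	1.2323e+03
5.1285e-02	1.0974e+03
5.3792e-02	9.7820e+02
5.6422e-02	8.7381e+02
5.9180e-02	7.8305e+02
6.2073e-02	7.0472e+02
6.5107e-02	6.3759e+02
6.8290e-02	5.8035e+02
7.1629e-02	5.3172e+02
7.5130e-02	4.9041e+02
7.8803e-02	4.5519e+02
8.2655e-02	4.2489e+02
8.6696e-02	3.9846e+02
9.0934e-02	3.7492e+02
9.5380e-02	3.5345e+02
1.0004e-01	3.3336e+02
1.0493e-01	3.1409e+02
1.1006e-01	2.9523e+02
1.1544e-01	2.7649e+02
1.2109e-01	2.5772e+02
1.2701e-01	2.3885e+02
1.3322e-01	2.1991e+02
1.3973e-01	2.0101e+02
1.4656e-01	1.8228e+02
1.5372e-01	1.6390e+02
1.6124e-01	1.4606e+02
1.6912e-01	1.2899e+02
1.7739e-01	1.1288e+02
1.8606e-01	9.7936e+01
1.9516e-01	8.4320e+01
2.0470e-01	7.2151e+01
2.1470e-01	6.1493e+01
2.2520e-01	5.2344e+01
2.3621e-01	4.4646e+01
2.4776e-01	3.8290e+01
2.5987e-01	3.3133e+01
2.7257e-01	2.9014e+01
2.8590e-01	2.5767e+01
2.9987e-01	2.3233e+01
3.1453e-01	2.1262e+01
3.2991e-01	1.9717e+01
3.4604e-01	1.8476e+01
3.6295e-01	1.7428e+01
3.8070e-01	1.6478e+01
3.9931e-01	1.5549e+01
4.1883e-01	1.4586e+01
4.3930e-01	1.3556e+01
4.6078e-01	1.2452e+01
4.8330e-01	1.1288e+01
5.0693e-01	1.0090e+01
5.3171e-01	8.8962e+00
5.5771e-01	7.7417e+00
5.8497e-01	6.6574e+00
6.1357e-01	5.6650e+00
6.4356e-01	4.7763e+00
6.7502e-01	3.9939e+00
7.0802e-01	3.3136e+00
7.4263e-01	2.7272e+00
7.7894e-01	2.2246e+00
8.1702e-01	1.7962e+00
8.5696e-01	1.4337e+00
8.9885e-01	1.1304e+00
9.4279e-01	8.8106e-01
9.8888e-01	6.8085e-01
1.0372e+00	5.2464e-01
1.0879e+00	4.0662e-01
1.1411e+00	3.2023e-01
1.1969e+00	2.5863e-01
1.2554e+00	2.1529e-01
1.3168e+00	1.8453e-01
1.3812e+00	1.6186e-01
1.4487e+00	1.4404e-01
1.5195e+00	1.2896e-01
1.5938e+00	1.1540e-01
1.6717e+00	1.0274e-01
1.7534e+00	9.0773e-02
1.8391e+00	7.9470e-02
1.9290e+00	6.8899e-02
2.0233e+00	5.9135e-02
2.1223e+00	5.0229e-02
2.2260e+00	4.2199e-02
2.3348e+00	3.5041e-02
2.4490e+00	2.8733e-02
2.5687e+00	2.3245e-02
2.6943e+00	1.8541e-02
2.8260e+00	1.4575e-02
2.9641e+00	1.1291e-02
3.1090e+00	8.6252e-03
3.2610e+00	6.5035e-03
3.4204e+00	4.8474e-03
3.5876e+00	3.5778e-03
3.7630e+00	2.6198e-03
3.9470e+00	1.9059e-03
4.1399e+00	1.3788e-03
4.3423e+00	9.9181e-04
4.5546e+00	7.0853e-04
4.7773e+00	5.0162e-04
5.0108e+00	3.5101e-04
5.2558e+00	2.4216e-04
5.5127e+00	1.6442e-04
5.7822e+00	1.0984e-04
6.0649e+00	7.2337e-05
6.3614e+00	4.7138e-05
6.6723e+00	3.0551e-05
6.9985e+00	1.9792e-05
7.3407e+00	1.2854e-05
7.6995e+00	8.3643e-06
8.0759e+00	5.4276e-06
8.4707e+00	3.4843e-06
8.8848e+00	2.1912e-06
9.3192e+00	1.3357e-06
9.7747e+00	7.8107e-07
1.0253e+01	4.3380e-07
1.0754e+01	2.2667e-07
1.1280e+01	1.1042e-07
1.1831e+01	4.9697e-08
1.2409e+01	2.0480e-08
1.3016e+01	7.6553e-09
1.3652e+01	2.5695e-09
1.4320e+01	7.6616e-10
1.5020e+01	2.0062e-10
1.5754e+01	4.5569e-11
1.6524e+01	8.8657e-12
1.7332e+01	1.4600e-12
1.8179e+01	2.0180e-13
1.9068e+01	2.3467e-14
2.0000e+01	2.3598e-15
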