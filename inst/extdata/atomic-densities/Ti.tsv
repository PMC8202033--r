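# element	Ti
# Z	22
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-848.032945
r_bohr	rho_e_bohr3
1.5000e-03	6.6811e+03
1.5733e-03	6.6585e+03
1.6502e-03	6.6350e+03
1.7309e-03	6.6106e+03
1.8155e-03	6.5853e+03
1.9043e-03	6.5591e+03
1.9974e-03	6.5319e+03
2.0950e-03	6.5038e+03
2.1974e-03	6.4746e+03
2.3049e-03	6.4443e+03
2.4175e-03	6.4128e+03
2.5357e-03	6.3801e+03
2.6597e-03	6.3459e+03
2.7897e-03	6.3103e+03
2.9261e-03	6.2731e+03
3.0691e-03	6.2342e+03
3.2192e-03	6.1936e+03
3.3765e-03	6.1511e+03
3.5416e-03	6.1068e+03
3.7148e-03	6.0605e+03
3.8964e-03	6.0122e+03
4.0868e-03	5.9618e+03
4.2866e-03	5.9095e+03
4.4962e-03	5.8550e+03
4.7160e-03	5.7985e+03
4.9465e-03	5.7398e+03
5.1883e-03	5.6790e+03
5.4420e-03	5.6160e+03
5.7080e-03	5.5507e+03
5.9871e-03	5.4830e+03
6.2797e-03	5.4131e+03
6.5867e-03	5.3407e+03
6.9087e-03	5.2658e+03
7.2465e-03	5.1884e+03
7.6007e-03	5.1085e+03
7.9723e-03	5.0259e+03
8.3620e-03	4.9408e+03
8.7708e-03	4.8530e+03
9.1996e-03	4.7626e+03
9.6493e-03	4.6696e+03
1.0121e-02	4.5739e+03
1.0616e-02	4.4757e+03
1.1135e-02	4.3750e+03
1.1679e-02	4.2719e+03
1.2250e-02	4.1663e+03
1.2849e-02	4.0584e+03
1.3477e-02	3.9483e+03
1.4136e-02	3.8361e+03
1.4827e-02	3.7218e+03
1.5552e-02	3.6057e+03
1.6312e-02	3.4879e+03
1.7109e-02	3.3686e+03
1.7946e-02	3.2478e+03
1.8823e-02	3.1259e+03
1.9743e-02	3.0030e+03
2.0709e-02	2.8794e+03
2.1721e-02	2.7553e+03
2.2783e-02	2.6310e+03
2.3897e-02	2.5068e+03
2.5065e-02	2.3829e+03
2.6290e-02	2.2597e+03
2.7575e-02	2.1376e+03
2.8923e-02	2.0167e+03
3.0337e-02	1.8975e+03
3.1820e-02	1.7802e+03
3.3376e-02	1.6653e+03
3.5008e-02	1.5530e+03
3.6719e-02	1.4437e+03
3.8514e-02	1.3378e+03
4.0397e-02	1.2354e+03
4.2372e-02	1.1368e+03
4.4443e-02	1.0425e+03
4.6616e-02	9.5242e+02
4.8894e-02	8.6695e+02
5.1285e-02	7.8624e+02
5.3792e-02	7.1041e+02
5.6422e-02	6.3956e+02
5.9180e-02	5.7375e+02
6.2073e-02	5.1300e+02
6.5107e-02	4.5725e+02
6.8290e-02	4.0645e+02
7.1629e-02	3.6047e+02
7.5130e-02	3.1916e+02
7.8803e-02	2.8232e+02
8.2655e-02	2.4974e+02
8.6696e-02	2.2116e+02
9.0934e-02	1.9629e+02
9.5380e-02	1.7482e+02
1.0004e-01	1.5643e+02
1.0493e-01	1.4078e+02
1.1006e-01	1.2754e+02
1.1544e-01	1.1639e+02
1.2109e-01	1.0699e+02
1.2701e-01	9.9061e+01
1.3322e-01	9.2306e+01
1.3973e-01	8.6474e+01
1.4656e-01	8.1335e+01
1.5372e-01	7.6693e+01
1.6124e-01	7.2384e+01
1.6912e-01	6.8274e+01
1.7739e-01	6.4263e+01
1.8606e-01	6.0279e+01
1.9516e-01	5.6275e+01
2.0470e-01	5.2230e+01
2.1470e-01	4.8141e+01
2.2520e-01	4.4027e+01
2.3621e-01	3.9920e+01
2.4776e-01	3.5863e+01
2.5987e-01	3.1906e+01
2.7257e-01	2.8100e+01
2.8590e-01	2.4491e+01
2.9987e-01	2.1120e+01
3.1453e-01	1.8017e+01
3.2991e-01	1.5204e+01
3.4604e-01	1.2691e+01
3.6295e-01	1.0484e+01
3.8070e-01	8.5796e+00
3.9931e-01	6.9678e+00
4.1883e-01	5.6336e+00
4.3930e-01	4.5555e+00
4.6078e-01	3.7071e+00
4.8330e-01	3.0578e+00
5.0693e-01	2.5749e+00
5.3171e-01	2.2251e+00
5.5771e-01	1.9769e+00
5.8497e-01	1.8025e+00
6.1357e-01	1.6780e+00
6.4356e-01	1.5845e+00
6.7502e-01	1.5076e+00
7.0802e-01	1.4367e+00
7.4263e-01	1.3646e+00
7.7894e-01	1.2869e+00
8.1702e-01	1.2014e+00
8.5696e-01	1.1077e+00
8.9885e-01	1.0071e+00
9.4279e-01	9.0203e-01
9.8888e-01	7.9551e-01
1.0372e+00	6.9080e-01
1.0879e+00	5.9094e-01
1.1411e+00	4.9840e-01
1.1969e+00	4.1488e-01
1.2554e+00	3.4127e-01
1.3168e+00	2.7776e-01
1.3812e+00	2.2395e-01
1.4487e+00	1.7906e-01
1.5195e+00	1.4210e-01
1.5938e+00	1.1204e-01
1.6717e+00	8.7862e-02
1.7534e+00	6.8643e-02
1.8391e+00	5.3570e-02
1.9290e+00	4.1924e-02
2.0233e+00	3.3067e-02
2.1223e+00	2.6430e-02
2.2260e+00	2.1509e-02
2.3348e+00	1.7865e-02
2.4490e+00	1.5132e-02
2.5687e+00	1.3020e-02
2.6943e+00	1.1313e-02
2.8260e+00	9.8651e-03
2.9641e+00	8.5847e-03
3.1090e+00	7.4226e-03
3.2610e+00	6.3580e-03
3.4204e+00	5.3861e-03
3.5876e+00	4.5091e-03
3.7630e+00	3.7298e-03
3.9470e+00	3.0487e-03
4.1399e+00	2.4628e-03
4.3423e+00	1.9663e-03
4.5546e+00	1.5511e-03
4.7773e+00	1.2082e-03
5.0108e+00	9.2845e-04
5.2558e+00	7.0298e-04
5.5127e+00	5.2358e-04
5.7822e+00	3.8290e-04
6.0649e+00	2.7442e-04
6.3614e+00	1.9238e-04
6.6723e+00	1.3172e-04
6.9985e+00	8.8002e-05
7.3407e+00	5.7350e-05
7.6995e+00	3.6472e-05
8.0759e+00	2.2662e-05
8.4707e+00	1.3781e-05
8.8848e+00	8.2175e-06
9.3192e+00	4.8134e-06
9.7747e+00	2.7723e-06
1.0253e+01	1.5697e-06
1.0754e+01	8.7210e-07
1.1280e+01	4.7369e-07
1.1831e+01	2.5011e-07
1.2409e+01	1.2742e-07
1.3016e+01	6.2083e-08
1.3652e+01	2.8646e-08
1.4320e+01	1.2388e-08
1.5020e+01	4.9685e-09
1.5754e+01	1.8283e-09
1.6524e+01	6.1065e-10
1.7332e+01	1.8306e-10
1.8179e+01	4.8684e-11
1.9068e+01	1.1343e-11
2.0000e+01	2.2846e-12
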