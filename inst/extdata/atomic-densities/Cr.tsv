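# element	Cr
# Z	24
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1043.311288
r_bohr	rho_e_bohr3
1.5000e-03	8.6671e+03
1.5733e-03	8.6354e+03
1.6502e-03	8.6026e+03
1.7309e-03	8.5686e+03
1.8155e-03	8.5333e+03
1.9043e-03	8.4968e+03
1.9974e-03	8.4589e+03
2.0950e-03	8.4196e+03
2.1974e-03	8.3788e+03
2.3049e-03	8.3363e+03
2.4175e-03	8.2921e+03
2.5357e-03	8.2459e+03
2.6597e-03	8.1977e+03
2.7897e-03	8.1474e+03
2.9261e-03	8.0947e+03
3.0691e-03	8.0397e+03
3.2192e-03	7.9823e+03
3.3765e-03	7.9223e+03
3.5416e-03	7.8597e+03
3.7148e-03	7.7945e+03
3.8964e-03	7.7267e+03
4.0868e-03	7.6561e+03
4.2866e-03	7.5828e+03
4.4962e-03	7.5067e+03
4.7160e-03	7.4277e+03
4.9465e-03	7.3459e+03
5.1883e-03	7.2612e+03
5.4420e-03	7.1734e+03
5.7080e-03	7.0826e+03
5.9871e-03	6.9887e+03
6.2797e-03	6.8915e+03
6.5867e-03	6.7911e+03
6.9087e-03	6.6873e+03
7.2465e-03	6.5801e+03
7.6007e-03	6.4695e+03
7.9723e-03	6.3555e+03
8.3620e-03	6.2381e+03
8.7708e-03	6.1173e+03
9.1996e-03	5.9931e+03
9.6493e-03	5.8655e+03
1.0121e-02	5.7346e+03
1.0616e-02	5.6005e+03
1.1135e-02	5.4632e+03
1.1679e-02	5.3229e+03
1.2250e-02	5.1796e+03
1.2849e-02	5.0335e+03
1.3477e-02	4.8849e+03
1.4136e-02	4.7337e+03
1.4827e-02	4.5803e+03
1.5552e-02	4.4248e+03
1.6312e-02	4.2674e+03
1.7109e-02	4.1085e+03
1.7946e-02	3.9483e+03
1.8823e-02	3.7871e+03
1.9743e-02	3.6252e+03
2.0709e-02	3.4629e+03
2.1721e-02	3.3008e+03
2.2783e-02	3.1390e+03
2.3897e-02	2.9781e+03
2.5065e-02	2.8183e+03
2.6290e-02	2.6603e+03
2.7575e-02	2.5043e+03
2.8923e-02	2.3508e+03
3.0337e-02	2.2002e+03
3.1820e-02	2.0531e+03
3.3376e-02	1.9098e+03
3.5008e-02	1.7707e+03
3.6719e-02	1.6363e+03
3.8514e-02	1.5069e+03
4.0397e-02	1.3829e+03
4.2372e-02	1.2645e+03
4.4443e-02	1.1520e+03
4.6616e-02	1.0457e+03
4.8894e-02	9.4571e+02
5.1285e-02	8.5225e+02
5.3792e-02	7.6537e+02
5.6422e-02	6.8510e+02
5.9180e-02	6.1140e+02
6.2073e-02	5.4416e+02
6.5107e-02	4.8325e+02
6.8290e-02	4.2847e+02
7.1629e-02	3.7956e+02
7.5130e-02	3.3625e+02
7.8803e-02	2.9820e+02
8.2655e-02	2.6505e+02
8.6696e-02	2.3639e+02
9.0934e-02	2.1180e+02
9.5380e-02	1.9085e+02
1.0004e-01	1.7310e+02
1.0493e-01	1.5810e+02
1.1006e-01	1.4545e+02
1.1544e-01	1.3473e+02
1.2109e-01	1.2558e+02
1.2701e-01	1.1765e+02
1.3322e-01	1.1064e+02
1.3973e-01	1.0430e+02
1.4656e-01	9.8394e+01
1.5372e-01	9.2757e+01
1.6124e-01	8.7253e+01
1.6912e-01	8.1789e+01
1.7739e-01	7.6305e+01
1.8606e-01	7.0774e+01
1.9516e-01	6.5194e+01
2.0470e-01	5.9589e+01
2.1470e-01	5.4001e+01
2.2520e-01	4.8488e+01
2.3621e-01	4.3117e+01
2.4776e-01	3.7959e+01
2.5987e-01	3.3079e+01
2.7257e-01	2.8534e+01
2.8590e-01	2.4366e+01
2.9987e-01	2.0605e+01
3.1453e-01	1.7263e+01
3.2991e-01	1.4342e+01
3.4604e-01	1.1831e+01
3.6295e-01	9.7134e+00
3.8070e-01	7.9627e+00
3.9931e-01	6.5483e+00
4.1883e-01	5.4339e+00
4.3930e-01	4.5790e+00
4.6078e-01	3.9405e+00
4.8330e-01	3.4745e+00
5.0693e-01	3.1395e+00
5.3171e-01	2.8979e+00
5.5771e-01	2.7179e+00
5.8497e-01	2.5746e+00
6.1357e-01	2.4492e+00
6.4356e-01	2.3287e+00
6.7502e-01	2.2047e+00
7.0802e-01	2.0725e+00
7.4263e-01	1.9299e+00
7.7894e-01	1.7770e+00
8.1702e-01	1.6156e+00
8.5696e-01	1.4487e+00
8.9885e-01	1.2803e+00
9.4279e-01	1.1148e+00
9.8888e-01	9.5671e-01
1.0372e+00	8.0972e-01
1.0879e+00	6.7668e-01
1.1411e+00	5.5926e-01
1.1969e+00	4.5793e-01
1.2554e+00	3.7219e-01
1.3168e+00	3.0074e-01
1.3812e+00	2.4185e-01
1.4487e+00	1.9364e-01
1.5195e+00	1.5430e-01
1.5938e+00	1.2224e-01
1.6717e+00	9.6171e-02
1.7534e+00	7.5090e-02
1.8391e+00	5.8206e-02
1.9290e+00	4.4877e-02
2.0233e+00	3.4540e-02
2.1223e+00	2.6671e-02
2.2260e+00	2.0776e-02
2.3348e+00	1.6404e-02
2.4490e+00	1.3159e-02
2.5687e+00	1.0715e-02
2.6943e+00	8.8242e-03
2.8260e+00	7.3096e-03
2.9641e+00	6.0552e-03
3.1090e+00	4.9915e-03
3.2610e+00	4.0808e-03
3.4204e+00	3.3040e-03
3.5876e+00	2.6495e-03
3.7630e+00	2.1070e-03
3.9470e+00	1.6646e-03
4.1399e+00	1.3082e-03
4.3423e+00	1.0235e-03
4.5546e+00	7.9673e-04
4.7773e+00	6.1625e-04
5.0108e+00	4.7264e-04
5.2558e+00	3.5858e-04
5.5127e+00	2.6840e-04
5.7822e+00	1.9771e-04
6.0649e+00	1.4297e-04
6.3614e+00	1.0128e-04
6.6723e+00	7.0166e-05
6.9985e+00	4.7490e-05
7.3407e+00	3.1392e-05
7.6995e+00	2.0274e-05
8.0759e+00	1.2806e-05
8.4707e+00	7.9224e-06
8.8848e+00	4.8081e-06
9.3192e+00	2.8660e-06
9.7747e+00	1.6788e-06
1.0253e+01	9.6554e-07
1.0754e+01	5.4404e-07
1.1280e+01	2.9910e-07
1.1831e+01	1.5950e-07
1.2409e+01	8.1894e-08
1.3016e+01	4.0132e-08
1.3652e+01	1.8593e-08
1.4320e+01	8.0622e-09
1.5020e+01	3.2388e-09
1.5754e+01	1.1930e-09
1.6524e+01	3.9867e-10
1.7332e+01	1.1955e-10
1.8179e+01	3.1796e-11
1.9068e+01	7.4090e-12
2.0000e+01	1.4922e-12
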