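# element	Fe
# Z	26
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1262.118519
r_bohr	rho_e_bohr3
1.5000e-03	1.1015e+04
1.5733e-03	1.0972e+04
1.6502e-03	1.0927e+04
1.7309e-03	1.0881e+04
1.8155e-03	1.0833e+04
1.9043e-03	1.0784e+04
1.9974e-03	1.0732e+04
2.0950e-03	1.0678e+04
2.1974e-03	1.0623e+04
2.3049e-03	1.0564e+04
2.4175e-03	1.0504e+04
2.5357e-03	1.0440e+04
2.6597e-03	1.0374e+04
2.7897e-03	1.0304e+04
2.9261e-03	1.0232e+04
3.0691e-03	1.0156e+04
3.2192e-03	1.0077e+04
3.3765e-03	9.9951e+03
3.5416e-03	9.9094e+03
3.7148e-03	9.8203e+03
3.8964e-03	9.7277e+03
4.0868e-03	9.6315e+03
4.2866e-03	9.5317e+03
4.4962e-03	9.4283e+03
4.7160e-03	9.3211e+03
4.9465e-03	9.2101e+03
5.1883e-03	9.0952e+03
5.4420e-03	8.9764e+03
5.7080e-03	8.8534e+03
5.9871e-03	8.7263e+03
6.2797e-03	8.5949e+03
6.5867e-03	8.4593e+03
6.9087e-03	8.3193e+03
7.2465e-03	8.1749e+03
7.6007e-03	8.0262e+03
7.9723e-03	7.8731e+03
8.3620e-03	7.7156e+03
8.7708e-03	7.5538e+03
9.1996e-03	7.3878e+03
9.6493e-03	7.2176e+03
1.0121e-02	7.0433e+03
1.0616e-02	6.8651e+03
1.1135e-02	6.6830e+03
1.1679e-02	6.4974e+03
1.2250e-02	6.3083e+03
1.2849e-02	6.1159e+03
1.3477e-02	5.9206e+03
1.4136e-02	5.7226e+03
1.4827e-02	5.5221e+03
1.5552e-02	5.3194e+03
1.6312e-02	5.1150e+03
1.7109e-02	4.9092e+03
1.7946e-02	4.7024e+03
1.8823e-02	4.4950e+03
1.9743e-02	4.2876e+03
2.0709e-02	4.0805e+03
2.1721e-02	3.8743e+03
2.2783e-02	3.6695e+03
2.3897e-02	3.4667e+03
2.5065e-02	3.2663e+03
2.6290e-02	3.0690e+03
2.7575e-02	2.8753e+03
2.8923e-02	2.6857e+03
3.0337e-02	2.5009e+03
3.1820e-02	2.3214e+03
3.3376e-02	2.1477e+03
3.5008e-02	1.9802e+03
3.6719e-02	1.8194e+03
3.8514e-02	1.6658e+03
4.0397e-02	1.5197e+03
4.2372e-02	1.3814e+03
4.4443e-02	1.2511e+03
4.6616e-02	1.1291e+03
4.8894e-02	1.0155e+03
5.1285e-02	9.1040e+02
5.3792e-02	8.1370e+02
5.6422e-02	7.2534e+02
5.9180e-02	6.4513e+02
6.2073e-02	5.7284e+02
6.5107e-02	5.0818e+02
6.8290e-02	4.5077e+02
7.1629e-02	4.0021e+02
7.5130e-02	3.5605e+02
7.8803e-02	3.1777e+02
8.2655e-02	2.8486e+02
8.6696e-02	2.5676e+02
9.0934e-02	2.3289e+02
9.5380e-02	2.1269e+02
1.0004e-01	1.9561e+02
1.0493e-01	1.8113e+02
1.1006e-01	1.6875e+02
1.1544e-01	1.5804e+02
1.2109e-01	1.4857e+02
1.2701e-01	1.4001e+02
1.3322e-01	1.3206e+02
1.3973e-01	1.2448e+02
1.4656e-01	1.1710e+02
1.5372e-01	1.0978e+02
1.6124e-01	1.0244e+02
1.6912e-01	9.5054e+01
1.7739e-01	8.7608e+01
1.8606e-01	8.0132e+01
1.9516e-01	7.2677e+01
2.0470e-01	6.5318e+01
2.1470e-01	5.8140e+01
2.2520e-01	5.1237e+01
2.3621e-01	4.4699e+01
2.4776e-01	3.8608e+01
2.5987e-01	3.3027e+01
2.7257e-01	2.7999e+01
2.8590e-01	2.3545e+01
2.9987e-01	1.9664e+01
3.1453e-01	1.6341e+01
3.2991e-01	1.3544e+01
3.4604e-01	1.1236e+01
3.6295e-01	9.3704e+00
3.8070e-01	7.8964e+00
3.9931e-01	6.7599e+00
4.1883e-01	5.9040e+00
4.3930e-01	5.2716e+00
4.6078e-01	4.8079e+00
4.8330e-01	4.4630e+00
5.0693e-01	4.1944e+00
5.3171e-01	3.9687e+00
5.5771e-01	3.7615e+00
5.8497e-01	3.5569e+00
6.1357e-01	3.3456e+00
6.4356e-01	3.1235e+00
6.7502e-01	2.8899e+00
7.0802e-01	2.6460e+00
7.4263e-01	2.3947e+00
7.7894e-01	2.1394e+00
8.1702e-01	1.8848e+00
8.5696e-01	1.6359e+00
8.9885e-01	1.3979e+00
9.4279e-01	1.1757e+00
9.8888e-01	9.7378e-01
1.0372e+00	7.9500e-01
1.0879e+00	6.4090e-01
1.1411e+00	5.1144e-01
1.1969e+00	4.0519e-01
1.2554e+00	3.1974e-01
1.3168e+00	2.5205e-01
1.3812e+00	1.9895e-01
1.4487e+00	1.5742e-01
1.5195e+00	1.2486e-01
1.5938e+00	9.9172e-02
1.6717e+00	7.8792e-02
1.7534e+00	6.2591e-02
1.8391e+00	4.9764e-02
1.9290e+00	3.9708e-02
2.0233e+00	3.1925e-02
2.1223e+00	2.5967e-02
2.2260e+00	2.1429e-02
2.3348e+00	1.7947e-02
2.4490e+00	1.5220e-02
2.5687e+00	1.3016e-02
2.6943e+00	1.1169e-02
2.8260e+00	9.5694e-03
2.9641e+00	8.1543e-03
3.1090e+00	6.8891e-03
3.2610e+00	5.7582e-03
3.4204e+00	4.7559e-03
3.5876e+00	3.8796e-03
3.7630e+00	3.1257e-03
3.9470e+00	2.4879e-03
4.1399e+00	1.9569e-03
4.3423e+00	1.5212e-03
4.5546e+00	1.1684e-03
4.7773e+00	8.8599e-04
5.0108e+00	6.6237e-04
5.2558e+00	4.8721e-04
5.5127e+00	3.5165e-04
5.7822e+00	2.4823e-04
6.0649e+00	1.7076e-04
6.3614e+00	1.1406e-04
6.6723e+00	7.3718e-05
6.9985e+00	4.5975e-05
7.3407e+00	2.7619e-05
7.6995e+00	1.5978e-05
8.0759e+00	8.9148e-06
8.4707e+00	4.8149e-06
8.8848e+00	2.5315e-06
9.3192e+00	1.3046e-06
9.7747e+00	6.6362e-07
1.0253e+01	3.3498e-07
1.0754e+01	1.6820e-07
1.1280e+01	8.3929e-08
1.1831e+01	4.1418e-08
1.2409e+01	2.0054e-08
1.3016e+01	9.4256e-09
1.3652e+01	4.2466e-09
1.4320e+01	1.8097e-09
1.5020e+01	7.1965e-10
1.5754e+01	2.6362e-10
1.6524e+01	8.7852e-11
1.7332e+01	2.6310e-11
1.8179e+01	6.9939e-12
1.9068e+01	1.6293e-12
2.0000e+01	3.2814e-13
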