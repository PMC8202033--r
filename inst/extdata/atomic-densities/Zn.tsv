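# element	Zn
# Z	30
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1777.675833
r_bohr	rho_e_bohr3
1.5000e-03	1.6853e+04
1.5733e-03	1.6779e+04
1.6502e-03	1.6702e+04
1.7309e-03	1.6622e+04
1.8155e-03	1.6539e+04
1.9043e-03	1.6453e+04
1.9974e-03	1.6362e+04
2.0950e-03	1.6268e+04
2.1974e-03	1.6170e+04
2.3049e-03	1.6067e+04
2.4175e-03	1.5960e+04
2.5357e-03	1.5848e+04
2.6597e-03	1.5731e+04
2.7897e-03	1.5608e+04
2.9261e-03	1.5481e+04
3.0691e-03	1.5348e+04
3.2192e-03	1.5210e+04
3.3765e-03	1.5067e+04
3.5416e-03	1.4918e+04
3.7148e-03	1.4763e+04
3.8964e-03	1.4603e+04
4.0868e-03	1.4437e+04
4.2866e-03	1.4265e+04
4.4962e-03	1.4087e+04
4.7160e-03	1.3903e+04
4.9465e-03	1.3713e+04
5.1883e-03	1.3516e+04
5.4420e-03	1.3312e+04
5.7080e-03	1.3102e+04
5.9871e-03	1.2885e+04
6.2797e-03	1.2662e+04
6.5867e-03	1.2431e+04
6.9087e-03	1.2194e+04
7.2465e-03	1.1950e+04
7.6007e-03	1.1700e+04
7.9723e-03	1.1442e+04
8.3620e-03	1.1179e+04
8.7708e-03	1.0909e+04
9.1996e-03	1.0633e+04
9.6493e-03	1.0351e+04
1.0121e-02	1.0063e+04
1.0616e-02	9.7703e+03
1.1135e-02	9.4724e+03
1.1679e-02	9.1698e+03
1.2250e-02	8.8631e+03
1.2849e-02	8.5525e+03
1.3477e-02	8.2387e+03
1.4136e-02	7.9221e+03
1.4827e-02	7.6033e+03
1.5552e-02	7.2830e+03
1.6312e-02	6.9618e+03
1.7109e-02	6.6405e+03
1.7946e-02	6.3198e+03
1.8823e-02	6.0005e+03
1.9743e-02	5.6834e+03
2.0709e-02	5.3694e+03
2.1721e-02	5.0592e+03
2.2783e-02	4.7537e+03
2.3897e-02	4.4539e+03
2.5065e-02	4.1605e+03
2.6290e-02	3.8744e+03
2.7575e-02	3.5966e+03
2.8923e-02	3.3278e+03
3.0337e-02	3.0688e+03
3.1820e-02	2.8202e+03
3.3376e-02	2.5826e+03
3.5008e-02	2.3567e+03
3.6719e-02	2.1430e+03
3.8514e-02	1.9417e+03
4.0397e-02	1.7532e+03
4.2372e-02	1.5778e+03
4.4443e-02	1.4155e+03
4.6616e-02	1.2663e+03
4.8894e-02	1.1300e+03
5.1285e-02	1.0064e+03
5.3792e-02	8.9506e+02
5.6422e-02	7.9547e+02
5.9180e-02	7.0709e+02
6.2073e-02	6.2926e+02
6.5107e-02	5.6127e+02
6.8290e-02	5.0234e+02
7.1629e-02	4.5165e+02
7.5130e-02	4.0833e+02
7.8803e-02	3.7150e+02
8.2655e-02	3.4028e+02
8.6696e-02	3.1382e+02
9.0934e-02	2.9129e+02
9.5380e-02	2.7192e+02
1.0004e-01	2.5501e+02
1.0493e-01	2.3996e+02
1.1006e-01	2.2621e+02
1.1544e-01	2.1333e+02
1.2109e-01	2.0096e+02
1.2701e-01	1.8883e+02
1.3322e-01	1.7678e+02
1.3973e-01	1.6468e+02
1.4656e-01	1.5252e+02
1.5372e-01	1.4030e+02
1.6124e-01	1.2809e+02
1.6912e-01	1.1597e+02
1.7739e-01	1.0407e+02
1.8606e-01	9.2513e+01
1.9516e-01	8.1458e+01
2.0470e-01	7.1043e+01
2.1470e-01	6.1397e+01
2.2520e-01	5.2622e+01
2.3621e-01	4.4786e+01
2.4776e-01	3.7918e+01
2.5987e-01	3.2008e+01
2.7257e-01	2.7013e+01
2.8590e-01	2.2865e+01
2.9987e-01	1.9482e+01
3.1453e-01	1.6769e+01
3.2991e-01	1.4632e+01
3.4604e-01	1.2976e+01
3.6295e-01	1.1708e+01
3.8070e-01	1.0738e+01
3.9931e-01	9.9845e+00
4.1883e-01	9.3720e+00
4.3930e-01	8.8384e+00
4.6078e-01	8.3358e+00
4.8330e-01	7.8324e+00
5.0693e-01	7.3115e+00
5.3171e-01	6.7695e+00
5.5771e-01	6.2113e+00
5.8497e-01	5.6469e+00
6.1357e-01	5.0874e+00
6.4356e-01	4.5428e+00
6.7502e-01	4.0206e+00
7.0802e-01	3.5257e+00
7.4263e-01	3.0609e+00
7.7894e-01	2.6280e+00
8.1702e-01	2.2283e+00
8.5696e-01	1.8634e+00
8.9885e-01	1.5352e+00
9.4279e-01	1.2454e+00
9.8888e-01	9.9532e-01
1.0372e+00	7.8476e-01
1.0879e+00	6.1211e-01
1.1411e+00	4.7418e-01
1.1969e+00	3.6657e-01
1.2554e+00	2.8422e-01
1.3168e+00	2.2195e-01
1.3812e+00	1.7500e-01
1.4487e+00	1.3933e-01
1.5195e+00	1.1176e-01
1.5938e+00	8.9994e-02
1.6717e+00	7.2475e-02
1.7534e+00	5.8227e-02
1.8391e+00	4.6647e-02
1.9290e+00	3.7329e-02
2.0233e+00	2.9943e-02
2.1223e+00	2.4173e-02
2.2260e+00	1.9702e-02
2.3348e+00	1.6229e-02
2.4490e+00	1.3493e-02
2.5687e+00	1.1289e-02
2.6943e+00	9.4644e-03
2.8260e+00	7.9187e-03
2.9641e+00	6.5877e-03
3.1090e+00	5.4332e-03
3.2610e+00	4.4330e-03
3.4204e+00	3.5732e-03
3.5876e+00	2.8433e-03
3.7630e+00	2.2330e-03
3.9470e+00	1.7308e-03
4.1399e+00	1.3240e-03
4.3423e+00	9.9957e-04
4.5546e+00	7.4445e-04
4.7773e+00	5.4667e-04
5.0108e+00	3.9552e-04
5.2558e+00	2.8169e-04
5.5127e+00	1.9727e-04
5.7822e+00	1.3565e-04
6.0649e+00	9.1444e-05
6.3614e+00	6.0307e-05
6.6723e+00	3.8819e-05
6.9985e+00	2.4328e-05
7.3407e+00	1.4808e-05
7.6995e+00	8.7365e-06
8.0759e+00	4.9903e-06
8.4707e+00	2.7597e-06
8.8848e+00	1.4798e-06
9.3192e+00	7.7194e-07
9.7747e+00	3.9362e-07
1.0253e+01	1.9730e-07
1.0754e+01	9.7716e-08
1.1280e+01	4.7952e-08
1.1831e+01	2.3293e-08
1.2409e+01	1.1136e-08
1.3016e+01	5.1876e-09
1.3652e+01	2.3244e-09
1.4320e+01	9.8752e-10
1.5020e+01	3.9213e-10
1.5754e+01	1.4356e-10
1.6524e+01	4.7831e-11
1.7332e+01	1.4324e-11
1.8179e+01	3.8077e-12
1.9068e+01	8.8707e-13
2.0000e+01	1.7865e-13
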