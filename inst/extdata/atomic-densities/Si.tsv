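# element	Si
# Z	14
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-288.757015
r_bohr	rho_e_bohr3
1.5000e-03	1.6950e+03
1.5733e-03	1.6915e+03
1.6502e-03	1.6879e+03
1.7309e-03	1.6840e+03
1.8155e-03	1.6799e+03
1.9043e-03	1.6756e+03
1.9974e-03	1.6711e+03
2.0950e-03	1.6663e+03
2.1974e-03	1.6612e+03
2.3049e-03	1.6560e+03
2.4175e-03	1.6505e+03
2.5357e-03	1.6448e+03
2.6597e-03	1.6389e+03
2.7897e-03	1.6328e+03
2.9261e-03	1.6264e+03
3.0691e-03	1.6198e+03
3.2192e-03	1.6130e+03
3.3765e-03	1.6059e+03
3.5416e-03	1.5985e+03
3.7148e-03	1.5909e+03
3.8964e-03	1.5830e+03
4.0868e-03	1.5747e+03
4.2866e-03	1.5661e+03
4.4962e-03	1.5570e+03
4.7160e-03	1.5476e+03
4.9465e-03	1.5377e+03
5.1883e-03	1.5274e+03
5.4420e-03	1.5167e+03
5.7080e-03	1.5054e+03
5.9871e-03	1.4937e+03
6.2797e-03	1.4814e+03
6.5867e-03	1.4687e+03
6.9087e-03	1.4555e+03
7.2465e-03	1.4417e+03
7.6007e-03	1.4275e+03
7.9723e-03	1.4127e+03
8.3620e-03	1.3974e+03
8.7708e-03	1.3815e+03
9.1996e-03	1.3651e+03
9.6493e-03	1.3481e+03
1.0121e-02	1.3304e+03
1.0616e-02	1.3122e+03
1.1135e-02	1.2934e+03
1.1679e-02	1.2739e+03
1.2250e-02	1.2538e+03
1.2849e-02	1.2330e+03
1.3477e-02	1.2116e+03
1.4136e-02	1.1895e+03
1.4827e-02	1.1668e+03
1.5552e-02	1.1434e+03
1.6312e-02	1.1195e+03
1.7109e-02	1.0948e+03
1.7946e-02	1.0696e+03
1.8823e-02	1.0438e+03
1.9743e-02	1.0174e+03
2.0709e-02	9.9039e+02
2.1721e-02	9.6288e+02
2.2783e-02	9.3487e+02
2.3897e-02	9.0637e+02
2.5065e-02	8.7743e+02
2.6290e-02	8.4807e+02
2.7575e-02	8.1835e+02
2.8923e-02	7.8831e+02
3.0337e-02	7.5800e+02
3.1820e-02	7.2748e+02
3.3376e-02	6.9681e+02
3.5008e-02	6.6605e+02
3.6719e-02	6.3528e+02
3.8514e-02	6.0455e+02
4.0397e-02	5.7395e+02
4.2372e-02	5.4354e+02
4.4443e-02	5.1342e+02
4.6616e-02	4.8366e+02
4.8894e-02	4.5434e+02
5.1285e-02	4.2555e+02
5.3792e-02	3.9736e+02
5.6422e-02	3.6986e+02
5.9180e-02	3.4312e+02
6.2073e-02	3.1722e+02
6.5107e-02	2.9222e+02
6.8290e-02	2.6820e+02
7.1629e-02	2.4522e+02
7.5130e-02	2.2332e+02
7.8803e-02	2.0257e+02
8.2655e-02	1.8300e+02
8.6696e-02	1.6463e+02
9.0934e-02	1.4749e+02
9.5380e-02	1.3159e+02
1.0004e-01	1.1692e+02
1.0493e-01	1.0348e+02
1.1006e-01	9.1253e+01
1.1544e-01	8.0202e+01
1.2109e-01	7.0290e+01
1.2701e-01	6.1468e+01
1.3322e-01	5.3679e+01
1.3973e-01	4.6858e+01
1.4656e-01	4.0937e+01
1.5372e-01	3.5843e+01
1.6124e-01	3.1500e+01
1.6912e-01	2.7829e+01
1.7739e-01	2.4752e+01
1.8606e-01	2.2193e+01
1.9516e-01	2.0076e+01
2.0470e-01	1.8330e+01
2.1470e-01	1.6888e+01
2.2520e-01	1.5690e+01
2.3621e-01	1.4682e+01
2.4776e-01	1.3816e+01
2.5987e-01	1.3051e+01
2.7257e-01	1.2355e+01
2.8590e-01	1.1698e+01
2.9987e-01	1.1062e+01
3.1453e-01	1.0431e+01
3.2991e-01	9.7969e+00
3.4604e-01	9.1546e+00
3.6295e-01	8.5037e+00
3.8070e-01	7.8466e+00
3.9931e-01	7.1873e+00
4.1883e-01	6.5316e+00
4.3930e-01	5.8856e+00
4.6078e-01	5.2561e+00
4.8330e-01	4.6501e+00
5.0693e-01	4.0738e+00
5.3171e-01	3.5332e+00
5.5771e-01	3.0330e+00
5.8497e-01	2.5766e+00
6.1357e-01	2.1658e+00
6.4356e-01	1.8013e+00
6.7502e-01	1.4821e+00
7.0802e-01	1.2063e+00
7.4263e-01	9.7125e-01
7.7894e-01	7.7378e-01
8.1702e-01	6.1040e-01
8.5696e-01	4.7747e-01
8.9885e-01	3.7128e-01
9.4279e-01	2.8809e-01
9.8888e-01	2.2425e-01
1.0372e+00	1.7625e-01
1.0879e+00	1.4086e-01
1.1411e+00	1.1520e-01
1.1969e+00	9.6819e-02
1.2554e+00	8.3695e-02
1.3168e+00	7.4245e-02
1.3812e+00	6.7259e-02
1.4487e+00	6.1842e-02
1.5195e+00	5.7354e-02
1.5938e+00	5.3352e-02
1.6717e+00	4.9551e-02
1.7534e+00	4.5785e-02
1.8391e+00	4.1981e-02
1.9290e+00	3.8132e-02
2.0233e+00	3.4274e-02
2.1223e+00	3.0466e-02
2.2260e+00	2.6774e-02
2.3348e+00	2.3259e-02
2.4490e+00	1.9971e-02
2.5687e+00	1.6949e-02
2.6943e+00	1.4216e-02
2.8260e+00	1.1785e-02
2.9641e+00	9.6538e-03
3.1090e+00	7.8149e-03
3.2610e+00	6.2514e-03
3.4204e+00	4.9416e-03
3.5876e+00	3.8606e-03
3.7630e+00	2.9812e-03
3.9470e+00	2.2760e-03
4.1399e+00	1.7182e-03
4.3423e+00	1.2828e-03
4.5546e+00	9.4700e-04
4.7773e+00	6.9104e-04
5.0108e+00	4.9803e-04
5.2558e+00	3.5409e-04
5.5127e+00	2.4799e-04
5.7822e+00	1.7084e-04
6.0649e+00	1.1562e-04
6.3614e+00	7.6812e-05
6.6723e+00	5.0091e-05
6.9985e+00	3.2091e-05
7.3407e+00	2.0224e-05
7.6995e+00	1.2555e-05
8.0759e+00	7.6840e-06
8.4707e+00	4.6327e-06
8.8848e+00	2.7433e-06
9.3192e+00	1.5869e-06
9.7747e+00	8.8974e-07
1.0253e+01	4.7892e-07
1.0754e+01	2.4487e-07
1.1280e+01	1.1762e-07
1.1831e+01	5.2488e-08
1.2409e+01	2.1525e-08
1.3016e+01	8.0240e-09
1.3652e+01	2.6889e-09
1.4320e+01	8.0075e-10
1.5020e+01	2.0935e-10
1.5754e+01	4.7433e-11
1.6524e+01	9.1852e-12
1.7332e+01	1.4985e-12
1.8179e+01	2.0315e-13
1.9068e+01	2.2655e-14
2.0000e+01	2.0829e-15
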