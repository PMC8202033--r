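# element	Sc
# Z	21
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-759.538982
r_bohr	rho_e_bohr3
1.5000e-03	5.8085e+03
1.5733e-03	5.7898e+03
1.6502e-03	5.7702e+03
1.7309e-03	5.7498e+03
1.8155e-03	5.7287e+03
1.9043e-03	5.7067e+03
1.9974e-03	5.6840e+03
2.0950e-03	5.6604e+03
2.1974e-03	5.6360e+03
2.3049e-03	5.6107e+03
2.4175e-03	5.5844e+03
2.5357e-03	5.5571e+03
2.6597e-03	5.5287e+03
2.7897e-03	5.4991e+03
2.9261e-03	5.4682e+03
3.0691e-03	5.4359e+03
3.2192e-03	5.4022e+03
3.3765e-03	5.3669e+03
3.5416e-03	5.3301e+03
3.7148e-03	5.2916e+03
3.8964e-03	5.2514e+03
4.0868e-03	5.2095e+03
4.2866e-03	5.1658e+03
4.4962e-03	5.1204e+03
4.7160e-03	5.0732e+03
4.9465e-03	5.0241e+03
5.1883e-03	4.9732e+03
5.4420e-03	4.9205e+03
5.7080e-03	4.8658e+03
5.9871e-03	4.8091e+03
6.2797e-03	4.7505e+03
6.5867e-03	4.6898e+03
6.9087e-03	4.6270e+03
7.2465e-03	4.5621e+03
7.6007e-03	4.4950e+03
7.9723e-03	4.4256e+03
8.3620e-03	4.3540e+03
8.7708e-03	4.2802e+03
9.1996e-03	4.2040e+03
9.6493e-03	4.1256e+03
1.0121e-02	4.0449e+03
1.0616e-02	3.9620e+03
1.1135e-02	3.8769e+03
1.1679e-02	3.7895e+03
1.2250e-02	3.7001e+03
1.2849e-02	3.6085e+03
1.3477e-02	3.5150e+03
1.4136e-02	3.4195e+03
1.4827e-02	3.3222e+03
1.5552e-02	3.2232e+03
1.6312e-02	3.1225e+03
1.7109e-02	3.0204e+03
1.7946e-02	2.9169e+03
1.8823e-02	2.8122e+03
1.9743e-02	2.7065e+03
2.0709e-02	2.6000e+03
2.1721e-02	2.4929e+03
2.2783e-02	2.3853e+03
2.3897e-02	2.2776e+03
2.5065e-02	2.1699e+03
2.6290e-02	2.0626e+03
2.7575e-02	1.9559e+03
2.8923e-02	1.8500e+03
3.0337e-02	1.7452e+03
3.1820e-02	1.6419e+03
3.3376e-02	1.5403e+03
3.5008e-02	1.4408e+03
3.6719e-02	1.3435e+03
3.8514e-02	1.2488e+03
4.0397e-02	1.1570e+03
4.2372e-02	1.0683e+03
4.4443e-02	9.8297e+02
4.6616e-02	9.0120e+02
4.8894e-02	8.2321e+02
5.1285e-02	7.4918e+02
5.3792e-02	6.7926e+02
5.6422e-02	6.1357e+02
5.9180e-02	5.5221e+02
6.2073e-02	4.9520e+02
6.5107e-02	4.4257e+02
6.8290e-02	3.9428e+02
7.1629e-02	3.5027e+02
7.5130e-02	3.1043e+02
7.8803e-02	2.7464e+02
8.2655e-02	2.4274e+02
8.6696e-02	2.1452e+02
9.0934e-02	1.8976e+02
9.5380e-02	1.6822e+02
1.0004e-01	1.4963e+02
1.0493e-01	1.3371e+02
1.1006e-01	1.2017e+02
1.1544e-01	1.0872e+02
1.2109e-01	9.9082e+01
1.2701e-01	9.0981e+01
1.3322e-01	8.4154e+01
1.3973e-01	7.8358e+01
1.4656e-01	7.3370e+01
1.5372e-01	6.8993e+01
1.6124e-01	6.5056e+01
1.6912e-01	6.1414e+01
1.7739e-01	5.7954e+01
1.8606e-01	5.4584e+01
1.9516e-01	5.1241e+01
2.0470e-01	4.7882e+01
2.1470e-01	4.4487e+01
2.2520e-01	4.1053e+01
2.3621e-01	3.7593e+01
2.4776e-01	3.4135e+01
2.5987e-01	3.0714e+01
2.7257e-01	2.7371e+01
2.8590e-01	2.4148e+01
2.9987e-01	2.1085e+01
3.1453e-01	1.8215e+01
3.2991e-01	1.5562e+01
3.4604e-01	1.3148e+01
3.6295e-01	1.0983e+01
3.8070e-01	9.0725e+00
3.9931e-01	7.4171e+00
4.1883e-01	6.0106e+00
4.3930e-01	4.8413e+00
4.6078e-01	3.8922e+00
4.8330e-01	3.1414e+00
5.0693e-01	2.5632e+00
5.3171e-01	2.1300e+00
5.5771e-01	1.8138e+00
5.8497e-01	1.5883e+00
6.1357e-01	1.4297e+00
6.4356e-01	1.3179e+00
6.7502e-01	1.2367e+00
7.0802e-01	1.1732e+00
7.4263e-01	1.1178e+00
7.7894e-01	1.0636e+00
8.1702e-01	1.0061e+00
8.5696e-01	9.4271e-01
8.9885e-01	8.7273e-01
9.4279e-01	7.9679e-01
9.8888e-01	7.1663e-01
1.0372e+00	6.3462e-01
1.0879e+00	5.5335e-01
1.1411e+00	4.7523e-01
1.1969e+00	4.0225e-01
1.2554e+00	3.3581e-01
1.3168e+00	2.7671e-01
1.3812e+00	2.2524e-01
1.4487e+00	1.8123e-01
1.5195e+00	1.4425e-01
1.5938e+00	1.1365e-01
1.6717e+00	8.8739e-02
1.7534e+00	6.8777e-02
1.8391e+00	5.3056e-02
1.9290e+00	4.0904e-02
2.0233e+00	3.1695e-02
2.1223e+00	2.4853e-02
2.2260e+00	1.9857e-02
2.3348e+00	1.6249e-02
2.4490e+00	1.3639e-02
2.5687e+00	1.1713e-02
2.6943e+00	1.0233e-02
2.8260e+00	9.0284e-03
2.9641e+00	7.9896e-03
3.1090e+00	7.0513e-03
3.2610e+00	6.1810e-03
3.4204e+00	5.3668e-03
3.5876e+00	4.6084e-03
3.7630e+00	3.9098e-03
3.9470e+00	3.2761e-03
4.1399e+00	2.7102e-03
4.3423e+00	2.2129e-03
4.5546e+00	1.7826e-03
4.7773e+00	1.4155e-03
5.0108e+00	1.1069e-03
5.2558e+00	8.5106e-04
5.5127e+00	6.4231e-04
5.7822e+00	4.7490e-04
6.0649e+00	3.4332e-04
6.3614e+00	2.4227e-04
6.6723e+00	1.6667e-04
6.9985e+00	1.1173e-04
7.3407e+00	7.2997e-05
7.6995e+00	4.6536e-05
8.0759e+00	2.9002e-05
8.4707e+00	1.7708e-05
8.8848e+00	1.0618e-05
9.3192e+00	6.2610e-06
9.7747e+00	3.6331e-06
1.0253e+01	2.0726e-06
1.0754e+01	1.1595e-06
1.1280e+01	6.3347e-07
1.1831e+01	3.3599e-07
1.2409e+01	1.7173e-07
1.3016e+01	8.3855e-08
1.3652e+01	3.8744e-08
1.4320e+01	1.6768e-08
1.5020e+01	6.7278e-09
1.5754e+01	2.4762e-09
1.6524e+01	8.2712e-10
1.7332e+01	2.4796e-10
1.8179e+01	6.5945e-11
1.9068e+01	1.5365e-11
2.0000e+01	3.0946e-12
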