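# element	Cu
# Z	29
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1638.822697
r_bohr	rho_e_bohr3
1.5000e-03	1.5235e+04
1.5733e-03	1.5169e+04
1.6502e-03	1.5102e+04
1.7309e-03	1.5032e+04
1.8155e-03	1.4959e+04
1.9043e-03	1.4883e+04
1.9974e-03	1.4804e+04
2.0950e-03	1.4722e+04
2.1974e-03	1.4636e+04
2.3049e-03	1.4546e+04
2.4175e-03	1.4452e+04
2.5357e-03	1.4354e+04
2.6597e-03	1.4252e+04
2.7897e-03	1.4145e+04
2.9261e-03	1.4034e+04
3.0691e-03	1.3918e+04
3.2192e-03	1.3797e+04
3.3765e-03	1.3671e+04
3.5416e-03	1.3540e+04
3.7148e-03	1.3404e+04
3.8964e-03	1.3264e+04
4.0868e-03	1.3118e+04
4.2866e-03	1.2967e+04
4.4962e-03	1.2810e+04
4.7160e-03	1.2648e+04
4.9465e-03	1.2481e+04
5.1883e-03	1.2307e+04
5.4420e-03	1.2128e+04
5.7080e-03	1.1943e+04
5.9871e-03	1.1752e+04
6.2797e-03	1.1555e+04
6.5867e-03	1.1351e+04
6.9087e-03	1.1142e+04
7.2465e-03	1.0927e+04
7.6007e-03	1.0705e+04
7.9723e-03	1.0477e+04
8.3620e-03	1.0244e+04
8.7708e-03	1.0005e+04
9.1996e-03	9.7599e+03
9.6493e-03	9.5095e+03
1.0121e-02	9.2539e+03
1.0616e-02	8.9933e+03
1.1135e-02	8.7280e+03
1.1679e-02	8.4583e+03
1.2250e-02	8.1845e+03
1.2849e-02	7.9070e+03
1.3477e-02	7.6263e+03
1.4136e-02	7.3426e+03
1.4827e-02	7.0567e+03
1.5552e-02	6.7689e+03
1.6312e-02	6.4800e+03
1.7109e-02	6.1904e+03
1.7946e-02	5.9010e+03
1.8823e-02	5.6123e+03
1.9743e-02	5.3250e+03
2.0709e-02	5.0400e+03
2.1721e-02	4.7578e+03
2.2783e-02	4.4794e+03
2.3897e-02	4.2055e+03
2.5065e-02	3.9368e+03
2.6290e-02	3.6742e+03
2.7575e-02	3.4184e+03
2.8923e-02	3.1703e+03
3.0337e-02	2.9305e+03
3.1820e-02	2.6996e+03
3.3376e-02	2.4783e+03
3.5008e-02	2.2671e+03
3.6719e-02	2.0666e+03
3.8514e-02	1.8770e+03
4.0397e-02	1.6989e+03
4.2372e-02	1.5323e+03
4.4443e-02	1.3775e+03
4.6616e-02	1.2345e+03
4.8894e-02	1.1033e+03
5.1285e-02	9.8371e+02
5.3792e-02	8.7540e+02
5.6422e-02	7.7801e+02
5.9180e-02	6.9110e+02
6.2073e-02	6.1414e+02
6.5107e-02	5.4651e+02
6.8290e-02	4.8757e+02
7.1629e-02	4.3660e+02
7.5130e-02	3.9284e+02
7.8803e-02	3.5552e+02
8.2655e-02	3.2383e+02
8.6696e-02	2.9698e+02
9.0934e-02	2.7422e+02
9.5380e-02	2.5482e+02
1.0004e-01	2.3811e+02
1.0493e-01	2.2347e+02
1.1006e-01	2.1037e+02
1.1544e-01	1.9834e+02
1.2109e-01	1.8702e+02
1.2701e-01	1.7609e+02
1.3322e-01	1.6534e+02
1.3973e-01	1.5464e+02
1.4656e-01	1.4388e+02
1.5372e-01	1.3306e+02
1.6124e-01	1.2220e+02
1.6912e-01	1.1135e+02
1.7739e-01	1.0060e+02
1.8606e-01	9.0067e+01
1.9516e-01	7.9870e+01
2.0470e-01	7.0144e+01
2.1470e-01	6.1013e+01
2.2520e-01	5.2587e+01
2.3621e-01	4.4951e+01
2.4776e-01	3.8153e+01
2.5987e-01	3.2211e+01
2.7257e-01	2.7108e+01
2.8590e-01	2.2802e+01
2.9987e-01	1.9232e+01
3.1453e-01	1.6325e+01
3.2991e-01	1.4000e+01
3.4604e-01	1.2174e+01
3.6295e-01	1.0767e+01
3.8070e-01	9.6947e+00
3.9931e-01	8.8803e+00
4.1883e-01	8.2506e+00
4.3930e-01	7.7411e+00
4.6078e-01	7.2990e+00
4.8330e-01	6.8847e+00
5.0693e-01	6.4728e+00
5.3171e-01	6.0502e+00
5.5771e-01	5.6136e+00
5.8497e-01	5.1662e+00
6.1357e-01	4.7142e+00
6.4356e-01	4.2646e+00
6.7502e-01	3.8237e+00
7.0802e-01	3.3963e+00
7.4263e-01	2.9860e+00
7.7894e-01	2.5959e+00
8.1702e-01	2.2287e+00
8.5696e-01	1.8875e+00
8.9885e-01	1.5755e+00
9.4279e-01	1.2956e+00
9.8888e-01	1.0502e+00
1.0372e+00	8.4017e-01
1.0879e+00	6.6502e-01
1.1411e+00	5.2248e-01
1.1969e+00	4.0904e-01
1.2554e+00	3.2036e-01
1.3168e+00	2.5182e-01
1.3812e+00	1.9899e-01
1.4487e+00	1.5804e-01
1.5195e+00	1.2585e-01
1.5938e+00	1.0012e-01
1.6717e+00	7.9276e-02
1.7534e+00	6.2283e-02
1.8391e+00	4.8498e-02
1.9290e+00	3.7475e-02
2.0233e+00	2.8839e-02
2.1223e+00	2.2222e-02
2.2260e+00	1.7249e-02
2.3348e+00	1.3554e-02
2.4490e+00	1.0809e-02
2.5687e+00	8.7414e-03
2.6943e+00	7.1450e-03
2.8260e+00	5.8719e-03
2.9641e+00	4.8254e-03
3.1090e+00	3.9462e-03
3.2610e+00	3.2008e-03
3.4204e+00	2.5708e-03
3.5876e+00	2.0444e-03
3.7630e+00	1.6113e-03
3.9470e+00	1.2606e-03
4.1399e+00	9.8015e-04
4.3423e+00	7.5764e-04
4.5546e+00	5.8191e-04
4.7773e+00	4.4343e-04
5.0108e+00	3.3460e-04
5.2558e+00	2.4946e-04
5.5127e+00	1.8335e-04
5.7822e+00	1.3257e-04
6.0649e+00	9.4103e-05
6.3614e+00	6.5450e-05
6.6723e+00	4.4527e-05
6.9985e+00	2.9591e-05
7.3407e+00	1.9193e-05
7.6995e+00	1.2147e-05
8.0759e+00	7.5063e-06
8.4707e+00	4.5345e-06
8.8848e+00	2.6828e-06
9.3192e+00	1.5579e-06
9.7747e+00	8.8937e-07
1.0253e+01	4.9953e-07
1.0754e+01	2.7575e-07
1.1280e+01	1.4912e-07
1.1831e+01	7.8546e-08
1.2409e+01	3.9986e-08
1.3016e+01	1.9488e-08
1.3652e+01	9.0000e-09
1.4320e+01	3.8960e-09
1.5020e+01	1.5639e-09
1.5754e+01	5.7586e-10
1.6524e+01	1.9242e-10
1.7332e+01	5.7697e-11
1.8179e+01	1.5346e-11
1.9068e+01	3.5759e-12
2.0000e+01	7.2022e-13
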