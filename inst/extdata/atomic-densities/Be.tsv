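# element	Be
# Z	4
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-14.573011
r_bohr	rho_e_bohr3
1.5000e-03	3.4732e+01
1.5733e-03	3.4723e+01
1.6502e-03	3.4715e+01
1.7309e-03	3.4705e+01
1.8155e-03	3.4694e+01
1.9043e-03	3.4683e+01
1.9974e-03	3.4670e+01
2.0950e-03	3.4656e+01
2.1974e-03	3.4641e+01
2.3049e-03	3.4625e+01
2.4175e-03	3.4607e+01
2.5357e-03	3.4587e+01
2.6597e-03	3.4565e+01
2.7897e-03	3.4542e+01
2.9261e-03	3.4516e+01
3.0691e-03	3.4488e+01
3.2192e-03	3.4458e+01
3.3765e-03	3.4425e+01
3.5416e-03	3.4390e+01
3.7148e-03	3.4351e+01
3.8964e-03	3.4309e+01
4.0868e-03	3.4264e+01
4.2866e-03	3.4216e+01
4.4962e-03	3.4164e+01
4.7160e-03	3.4108e+01
4.9465e-03	3.4048e+01
5.1883e-03	3.3984e+01
5.4420e-03	3.3916e+01
5.7080e-03	3.3843e+01
5.9871e-03	3.3766e+01
6.2797e-03	3.3685e+01
6.5867e-03	3.3599e+01
6.9087e-03	3.3508e+01
7.2465e-03	3.3413e+01
7.6007e-03	3.3314e+01
7.9723e-03	3.3210e+01
8.3620e-03	3.3102e+01
8.7708e-03	3.2989e+01
9.1996e-03	3.2872e+01
9.6493e-03	3.2751e+01
1.0121e-02	3.2626e+01
1.0616e-02	3.2496e+01
1.1135e-02	3.2362e+01
1.1679e-02	3.2223e+01
1.2250e-02	3.2078e+01
1.2849e-02	3.1928e+01
1.3477e-02	3.1771e+01
1.4136e-02	3.1607e+01
1.4827e-02	3.1436e+01
1.5552e-02	3.1258e+01
1.6312e-02	3.1070e+01
1.7109e-02	3.0874e+01
1.7946e-02	3.0669e+01
1.8823e-02	3.0455e+01
1.9743e-02	3.0231e+01
2.0709e-02	2.9998e+01
2.1721e-02	2.9756e+01
2.2783e-02	2.9504e+01
2.3897e-02	2.9242e+01
2.5065e-02	2.8971e+01
2.6290e-02	2.8689e+01
2.7575e-02	2.8398e+01
2.8923e-02	2.8096e+01
3.0337e-02	2.7783e+01
3.1820e-02	2.7458e+01
3.3376e-02	2.7122e+01
3.5008e-02	2.6774e+01
3.6719e-02	2.6413e+01
3.8514e-02	2.6040e+01
4.0397e-02	2.5654e+01
4.2372e-02	2.5255e+01
4.4443e-02	2.4843e+01
4.6616e-02	2.4419e+01
4.8894e-02	2.3982e+01
5.1285e-02	2.3533e+01
5.3792e-02	2.3071e+01
5.6422e-02	2.2596e+01
5.9180e-02	2.2110e+01
6.2073e-02	2.1611e+01
6.5107e-02	2.1100e+01
6.8290e-02	2.0578e+01
7.1629e-02	2.0045e+01
7.5130e-02	1.9500e+01
7.8803e-02	1.8945e+01
8.2655e-02	1.8381e+01
8.6696e-02	1.7807e+01
9.0934e-02	1.7226e+01
9.5380e-02	1.6636e+01
1.0004e-01	1.6040e+01
1.0493e-01	1.5439e+01
1.1006e-01	1.4833e+01
1.1544e-01	1.4224e+01
1.2109e-01	1.3613e+01
1.2701e-01	1.3001e+01
1.3322e-01	1.2389e+01
1.3973e-01	1.1780e+01
1.4656e-01	1.1173e+01
1.5372e-01	1.0572e+01
1.6124e-01	9.9762e+00
1.6912e-01	9.3886e+00
1.7739e-01	8.8104e+00
1.8606e-01	8.2432e+00
1.9516e-01	7.6884e+00
2.0470e-01	7.1475e+00
2.1470e-01	6.6220e+00
2.2520e-01	6.1133e+00
2.3621e-01	5.6225e+00
2.4776e-01	5.1510e+00
2.5987e-01	4.6998e+00
2.7257e-01	4.2698e+00
2.8590e-01	3.8618e+00
2.9987e-01	3.4765e+00
3.1453e-01	3.1144e+00
3.2991e-01	2.7757e+00
3.4604e-01	2.4606e+00
3.6295e-01	2.1691e+00
3.8070e-01	1.9010e+00
3.9931e-01	1.6559e+00
4.1883e-01	1.4332e+00
4.3930e-01	1.2322e+00
4.6078e-01	1.0521e+00
4.8330e-01	8.9188e-01
5.0693e-01	7.5048e-01
5.3171e-01	6.2671e-01
5.5771e-01	5.1929e-01
5.8497e-01	4.2694e-01
6.1357e-01	3.4831e-01
6.4356e-01	2.8205e-01
6.7502e-01	2.2685e-01
7.0802e-01	1.8140e-01
7.4263e-01	1.4447e-01
7.7894e-01	1.1488e-01
8.1702e-01	9.1518e-02
8.5696e-01	7.3378e-02
8.9885e-01	5.9539e-02
9.4279e-01	4.9179e-02
9.8888e-01	4.1579e-02
1.0372e+00	3.6117e-02
1.0879e+00	3.2265e-02
1.1411e+00	2.9583e-02
1.1969e+00	2.7715e-02
1.2554e+00	2.6376e-02
1.3168e+00	2.5348e-02
1.3812e+00	2.4468e-02
1.4487e+00	2.3622e-02
1.5195e+00	2.2734e-02
1.5938e+00	2.1758e-02
1.6717e+00	2.0676e-02
1.7534e+00	1.9484e-02
1.8391e+00	1.8194e-02
1.9290e+00	1.6827e-02
2.0233e+00	1.5408e-02
2.1223e+00	1.3964e-02
2.2260e+00	1.2523e-02
2.3348e+00	1.1111e-02
2.4490e+00	9.7509e-03
2.5687e+00	8.4629e-03
2.6943e+00	7.2622e-03
2.8260e+00	6.1601e-03
2.9641e+00	5.1638e-03
3.1090e+00	4.2762e-03
3.2610e+00	3.4972e-03
3.4204e+00	2.8234e-03
3.5876e+00	2.2491e-03
3.7630e+00	1.7670e-03
3.9470e+00	1.3685e-03
4.1399e+00	1.0441e-03
4.3423e+00	7.8442e-04
4.5546e+00	5.7990e-04
4.7773e+00	4.2157e-04
5.0108e+00	3.0115e-04
5.2558e+00	2.1123e-04
5.5127e+00	1.4535e-04
5.7822e+00	9.8026e-05
6.0649e+00	6.4740e-05
6.3614e+00	4.1831e-05
6.6723e+00	2.6419e-05
6.9985e+00	1.6294e-05
7.3407e+00	9.8021e-06
7.6995e+00	5.7445e-06
8.0759e+00	3.2742e-06
8.4707e+00	1.8114e-06
8.8848e+00	9.7039e-07
9.3192e+00	5.0217e-07
9.7747e+00	2.5048e-07
1.0253e+01	1.2024e-07
1.0754e+01	5.5530e-08
1.1280e+01	2.4695e-08
1.1831e+01	1.0600e-08
1.2409e+01	4.4039e-09
1.3016e+01	1.7749e-09
1.3652e+01	6.9374e-10
1.4320e+01	2.6190e-10
1.5020e+01	9.4669e-11
1.5754e+01	3.2345e-11
1.6524e+01	1.0282e-11
1.7332e+01	2.9890e-12
1.8179e+01	7.8091e-13
1.9068e+01	1.8022e-13
2.0000e+01	3.6125e-14
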