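# element	V
# Z	23
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-942.451038
r_bohr	rho_e_bohr3
1.5000e-03	7.6343e+03
1.5733e-03	7.6074e+03
1.6502e-03	7.5795e+03
1.7309e-03	7.5506e+03
1.8155e-03	7.5206e+03
1.9043e-03	7.4896e+03
1.9974e-03	7.4574e+03
2.0950e-03	7.4240e+03
2.1974e-03	7.3893e+03
2.3049e-03	7.3533e+03
2.4175e-03	7.3159e+03
2.5357e-03	7.2769e+03
2.6597e-03	7.2362e+03
2.7897e-03	7.1936e+03
2.9261e-03	7.1492e+03
3.0691e-03	7.1028e+03
3.2192e-03	7.0542e+03
3.3765e-03	7.0035e+03
3.5416e-03	6.9506e+03
3.7148e-03	6.8954e+03
3.8964e-03	6.8379e+03
4.0868e-03	6.7781e+03
4.2866e-03	6.7158e+03
4.4962e-03	6.6512e+03
4.7160e-03	6.5841e+03
4.9465e-03	6.5145e+03
5.1883e-03	6.4424e+03
5.4420e-03	6.3677e+03
5.7080e-03	6.2904e+03
5.9871e-03	6.2104e+03
6.2797e-03	6.1276e+03
6.5867e-03	6.0420e+03
6.9087e-03	5.9534e+03
7.2465e-03	5.8620e+03
7.6007e-03	5.7676e+03
7.9723e-03	5.6702e+03
8.3620e-03	5.5698e+03
8.7708e-03	5.4663e+03
9.1996e-03	5.3599e+03
9.6493e-03	5.2505e+03
1.0121e-02	5.1381e+03
1.0616e-02	5.0229e+03
1.1135e-02	4.9048e+03
1.1679e-02	4.7840e+03
1.2250e-02	4.6605e+03
1.2849e-02	4.5344e+03
1.3477e-02	4.4059e+03
1.4136e-02	4.2751e+03
1.4827e-02	4.1422e+03
1.5552e-02	4.0073e+03
1.6312e-02	3.8706e+03
1.7109e-02	3.7322e+03
1.7946e-02	3.5925e+03
1.8823e-02	3.4517e+03
1.9743e-02	3.3101e+03
2.0709e-02	3.1679e+03
2.1721e-02	3.0254e+03
2.2783e-02	2.8830e+03
2.3897e-02	2.7410e+03
2.5065e-02	2.5998e+03
2.6290e-02	2.4597e+03
2.7575e-02	2.3210e+03
2.8923e-02	2.1842e+03
3.0337e-02	2.0497e+03
3.1820e-02	1.9178e+03
3.3376e-02	1.7889e+03
3.5008e-02	1.6635e+03
3.6719e-02	1.5417e+03
3.8514e-02	1.4241e+03
4.0397e-02	1.3109e+03
4.2372e-02	1.2025e+03
4.4443e-02	1.0990e+03
4.6616e-02	1.0007e+03
4.8894e-02	9.0792e+02
5.1285e-02	8.2069e+02
5.3792e-02	7.3918e+02
5.6422e-02	6.6345e+02
5.9180e-02	5.9351e+02
6.2073e-02	5.2933e+02
6.5107e-02	4.7081e+02
6.8290e-02	4.1784e+02
7.1629e-02	3.7022e+02
7.5130e-02	3.2775e+02
7.8803e-02	2.9017e+02
8.2655e-02	2.5718e+02
8.6696e-02	2.2846e+02
9.0934e-02	2.0366e+02
9.5380e-02	1.8240e+02
1.0004e-01	1.6431e+02
1.0493e-01	1.4898e+02
1.1006e-01	1.3606e+02
1.1544e-01	1.2516e+02
1.2109e-01	1.1593e+02
1.2701e-01	1.0807e+02
1.3322e-01	1.0126e+02
1.3973e-01	9.5248e+01
1.4656e-01	8.9804e+01
1.5372e-01	8.4738e+01
1.6124e-01	7.9901e+01
1.6912e-01	7.5174e+01
1.7739e-01	7.0478e+01
1.8606e-01	6.5760e+01
1.9516e-01	6.0996e+01
2.0470e-01	5.6186e+01
2.1470e-01	5.1350e+01
2.2520e-01	4.6526e+01
2.3621e-01	4.1766e+01
2.4776e-01	3.7127e+01
2.5987e-01	3.2671e+01
2.7257e-01	2.8453e+01
2.8590e-01	2.4521e+01
2.9987e-01	2.0911e+01
3.1453e-01	1.7648e+01
3.2991e-01	1.4743e+01
3.4604e-01	1.2200e+01
3.6295e-01	1.0012e+01
3.8070e-01	8.1648e+00
3.9931e-01	6.6391e+00
4.1883e-01	5.4088e+00
4.3930e-01	4.4424e+00
4.6078e-01	3.7043e+00
4.8330e-01	3.1564e+00
5.0693e-01	2.7599e+00
5.3171e-01	2.4782e+00
5.5771e-01	2.2786e+00
5.8497e-01	2.1334e+00
6.1357e-01	2.0207e+00
6.4356e-01	1.9242e+00
6.7502e-01	1.8320e+00
7.0802e-01	1.7367e+00
7.4263e-01	1.6337e+00
7.7894e-01	1.5212e+00
8.1702e-01	1.3991e+00
8.5696e-01	1.2693e+00
8.9885e-01	1.1346e+00
9.4279e-01	9.9874e-01
9.8888e-01	8.6567e-01
1.0372e+00	7.3912e-01
1.0879e+00	6.2216e-01
1.1411e+00	5.1696e-01
1.1969e+00	4.2464e-01
1.2554e+00	3.4540e-01
1.3168e+00	2.7866e-01
1.3812e+00	2.2330e-01
1.4487e+00	1.7794e-01
1.5195e+00	1.4110e-01
1.5938e+00	1.1140e-01
1.6717e+00	8.7609e-02
1.7534e+00	6.8709e-02
1.8391e+00	5.3849e-02
1.9290e+00	4.2317e-02
2.0233e+00	3.3497e-02
2.1223e+00	2.6841e-02
2.2260e+00	2.1862e-02
2.3348e+00	1.8133e-02
2.4490e+00	1.5300e-02
2.5687e+00	1.3080e-02
2.6943e+00	1.1269e-02
2.8260e+00	9.7270e-03
2.9641e+00	8.3680e-03
3.1090e+00	7.1470e-03
3.2610e+00	6.0445e-03
3.4204e+00	5.0552e-03
3.5876e+00	4.1788e-03
3.7630e+00	3.4148e-03
3.9470e+00	2.7594e-03
4.1399e+00	2.2055e-03
4.3423e+00	1.7436e-03
4.5546e+00	1.3629e-03
4.7773e+00	1.0527e-03
5.0108e+00	8.0261e-04
5.2558e+00	6.0341e-04
5.5127e+00	4.4671e-04
5.7822e+00	3.2513e-04
6.0649e+00	2.3229e-04
6.3614e+00	1.6263e-04
6.6723e+00	1.1141e-04
6.9985e+00	7.4597e-05
7.3407e+00	4.8780e-05
7.6995e+00	3.1149e-05
8.0759e+00	1.9433e-05
8.4707e+00	1.1858e-05
8.8848e+00	7.0876e-06
9.3192e+00	4.1565e-06
9.7747e+00	2.3944e-06
1.0253e+01	1.3551e-06
1.0754e+01	7.5241e-07
1.1280e+01	4.0845e-07
1.1831e+01	2.1560e-07
1.2409e+01	1.0983e-07
1.3016e+01	5.3519e-08
1.3652e+01	2.4699e-08
1.4320e+01	1.0684e-08
1.5020e+01	4.2854e-09
1.5754e+01	1.5772e-09
1.6524e+01	5.2681e-10
1.7332e+01	1.5794e-10
1.8179e+01	4.2003e-11
1.9068e+01	9.7868e-12
2.0000e+01	1.9711e-12
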