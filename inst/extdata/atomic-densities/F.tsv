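# element	F
# Z	9
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-99.164611
r_bohr	rho_e_bohr3
1.5000e-03	4.3635e+02
1.5733e-03	4.3590e+02
1.6502e-03	4.3542e+02
1.7309e-03	4.3490e+02
1.8155e-03	4.3434e+02
1.9043e-03	4.3373e+02
1.9974e-03	4.3308e+02
2.0950e-03	4.3238e+02
2.1974e-03	4.3163e+02
2.3049e-03	4.3083e+02
2.4175e-03	4.2997e+02
2.5357e-03	4.2906e+02
2.6597e-03	4.2809e+02
2.7897e-03	4.2706e+02
2.9261e-03	4.2597e+02
3.0691e-03	4.2483e+02
3.2192e-03	4.2363e+02
3.3765e-03	4.2237e+02
3.5416e-03	4.2105e+02
3.7148e-03	4.1967e+02
3.8964e-03	4.1824e+02
4.0868e-03	4.1675e+02
4.2866e-03	4.1521e+02
4.4962e-03	4.1361e+02
4.7160e-03	4.1196e+02
4.9465e-03	4.1024e+02
5.1883e-03	4.0847e+02
5.4420e-03	4.0662e+02
5.7080e-03	4.0471e+02
5.9871e-03	4.0271e+02
6.2797e-03	4.0064e+02
6.5867e-03	3.9847e+02
6.9087e-03	3.9620e+02
7.2465e-03	3.9383e+02
7.6007e-03	3.9136e+02
7.9723e-03	3.8876e+02
8.3620e-03	3.8605e+02
8.7708e-03	3.8322e+02
9.1996e-03	3.8027e+02
9.6493e-03	3.7719e+02
1.0121e-02	3.7399e+02
1.0616e-02	3.7066e+02
1.1135e-02	3.6721e+02
1.1679e-02	3.6363e+02
1.2250e-02	3.5991e+02
1.2849e-02	3.5606e+02
1.3477e-02	3.5207e+02
1.4136e-02	3.4794e+02
1.4827e-02	3.4366e+02
1.5552e-02	3.3923e+02
1.6312e-02	3.3465e+02
1.7109e-02	3.2991e+02
1.7946e-02	3.2500e+02
1.8823e-02	3.1993e+02
1.9743e-02	3.1470e+02
2.0709e-02	3.0931e+02
2.1721e-02	3.0375e+02
2.2783e-02	2.9802e+02
2.3897e-02	2.9213e+02
2.5065e-02	2.8609e+02
2.6290e-02	2.7988e+02
2.7575e-02	2.7352e+02
2.8923e-02	2.6700e+02
3.0337e-02	2.6034e+02
3.1820e-02	2.5354e+02
3.3376e-02	2.4659e+02
3.5008e-02	2.3952e+02
3.6719e-02	2.3232e+02
3.8514e-02	2.2500e+02
4.0397e-02	2.1758e+02
4.2372e-02	2.1006e+02
4.4443e-02	2.0245e+02
4.6616e-02	1.9478e+02
4.8894e-02	1.8704e+02
5.1285e-02	1.7926e+02
5.3792e-02	1.7146e+02
5.6422e-02	1.6364e+02
5.9180e-02	1.5583e+02
6.2073e-02	1.4805e+02
6.5107e-02	1.4031e+02
6.8290e-02	1.3263e+02
7.1629e-02	1.2504e+02
7.5130e-02	1.1755e+02
7.8803e-02	1.1019e+02
8.2655e-02	1.0297e+02
8.6696e-02	9.5917e+01
9.0934e-02	8.9048e+01
9.5380e-02	8.2381e+01
1.0004e-01	7.5937e+01
1.0493e-01	6.9732e+01
1.1006e-01	6.3782e+01
1.1544e-01	5.8100e+01
1.2109e-01	5.2699e+01
1.2701e-01	4.7590e+01
1.3322e-01	4.2781e+01
1.3973e-01	3.8278e+01
1.4656e-01	3.4085e+01
1.5372e-01	3.0203e+01
1.6124e-01	2.6631e+01
1.6912e-01	2.3365e+01
1.7739e-01	2.0399e+01
1.8606e-01	1.7724e+01
1.9516e-01	1.5330e+01
2.0470e-01	1.3204e+01
2.1470e-01	1.1331e+01
2.2520e-01	9.6955e+00
2.3621e-01	8.2806e+00
2.4776e-01	7.0680e+00
2.5987e-01	6.0390e+00
2.7257e-01	5.1745e+00
2.8590e-01	4.4557e+00
2.9987e-01	3.8643e+00
3.1453e-01	3.3826e+00
3.2991e-01	2.9938e+00
3.4604e-01	2.6824e+00
3.6295e-01	2.4339e+00
3.8070e-01	2.2356e+00
3.9931e-01	2.0759e+00
4.1883e-01	1.9452e+00
4.3930e-01	1.8353e+00
4.6078e-01	1.7394e+00
4.8330e-01	1.6522e+00
5.0693e-01	1.5697e+00
5.3171e-01	1.4889e+00
5.5771e-01	1.4079e+00
5.8497e-01	1.3256e+00
6.1357e-01	1.2415e+00
6.4356e-01	1.1557e+00
6.7502e-01	1.0687e+00
7.0802e-01	9.8136e-01
7.4263e-01	8.9455e-01
7.7894e-01	8.0924e-01
8.1702e-01	7.2636e-01
8.5696e-01	6.4676e-01
8.9885e-01	5.7120e-01
9.4279e-01	5.0029e-01
9.8888e-01	4.3451e-01
1.0372e+00	3.7419e-01
1.0879e+00	3.1951e-01
1.1411e+00	2.7052e-01
1.1969e+00	2.2710e-01
1.2554e+00	1.8904e-01
1.3168e+00	1.5601e-01
1.3812e+00	1.2764e-01
1.4487e+00	1.0351e-01
1.5195e+00	8.3178e-02
1.5938e+00	6.6225e-02
1.6717e+00	5.2235e-02
1.7534e+00	4.0817e-02
1.8391e+00	3.1600e-02
1.9290e+00	2.4244e-02
2.0233e+00	1.8435e-02
2.1223e+00	1.3892e-02
2.2260e+00	1.0374e-02
2.3348e+00	7.6720e-03
2.4490e+00	5.6166e-03
2.5687e+00	4.0679e-03
2.6943e+00	2.9136e-03
2.8260e+00	2.0636e-03
2.9641e+00	1.4456e-03
3.1090e+00	1.0020e-03
3.2610e+00	6.8749e-04
3.4204e+00	4.6691e-04
3.5876e+00	3.1367e-04
3.7630e+00	2.0815e-04
3.9470e+00	1.3619e-04
4.1399e+00	8.7677e-05
4.3423e+00	5.5446e-05
4.5546e+00	3.4418e-05
4.7773e+00	2.0981e-05
5.0108e+00	1.2579e-05
5.2558e+00	7.4322e-06
5.5127e+00	4.3337e-06
5.7822e+00	2.4937e-06
6.0649e+00	1.4126e-06
6.3614e+00	7.8376e-07
6.6723e+00	4.2300e-07
6.9985e+00	2.2033e-07
7.3407e+00	1.0995e-07
7.6995e+00	5.2261e-08
8.0759e+00	2.3601e-08
8.4707e+00	1.0143e-08
8.8848e+00	4.1766e-09
9.3192e+00	1.6684e-09
9.7747e+00	6.5733e-10
1.0253e+01	2.5964e-10
1.0754e+01	1.0385e-10
1.1280e+01	4.1980e-11
1.1831e+01	1.6903e-11
1.2409e+01	6.6326e-12
1.3016e+01	2.4800e-12
1.3652e+01	8.6826e-13
1.4320e+01	2.8180e-13
1.5020e+01	8.4645e-14
1.5754e+01	2.3672e-14
1.6524e+01	6.2239e-15
1.7332e+01	1.5478e-15
1.8179e+01	3.6200e-16
1.9068e+01	7.8059e-17
2.0000e+01	1.5088e-17
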