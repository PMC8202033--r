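# element	Na
# Z	11
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-161.858723
r_bohr	rho_e_bohr3
1.5000e-03	8.0699e+02
1.5733e-03	8.0585e+02
1.6502e-03	8.0463e+02
1.7309e-03	8.0331e+02
1.8155e-03	8.0190e+02
1.9043e-03	8.0039e+02
1.9974e-03	7.9878e+02
2.0950e-03	7.9706e+02
2.1974e-03	7.9524e+02
2.3049e-03	7.9331e+02
2.4175e-03	7.9127e+02
2.5357e-03	7.8912e+02
2.6597e-03	7.8686e+02
2.7897e-03	7.8450e+02
2.9261e-03	7.8203e+02
3.0691e-03	7.7945e+02
3.2192e-03	7.7677e+02
3.3765e-03	7.7398e+02
3.5416e-03	7.7109e+02
3.7148e-03	7.6809e+02
3.8964e-03	7.6499e+02
4.0868e-03	7.6177e+02
4.2866e-03	7.5844e+02
4.4962e-03	7.5499e+02
4.7160e-03	7.5139e+02
4.9465e-03	7.4766e+02
5.1883e-03	7.4376e+02
5.4420e-03	7.3969e+02
5.7080e-03	7.3545e+02
5.9871e-03	7.3100e+02
6.2797e-03	7.2636e+02
6.5867e-03	7.2150e+02
6.9087e-03	7.1642e+02
7.2465e-03	7.1111e+02
7.6007e-03	7.0558e+02
7.9723e-03	6.9982e+02
8.3620e-03	6.9382e+02
8.7708e-03	6.8759e+02
9.1996e-03	6.8112e+02
9.6493e-03	6.7440e+02
1.0121e-02	6.6744e+02
1.0616e-02	6.6023e+02
1.1135e-02	6.5275e+02
1.1679e-02	6.4502e+02
1.2250e-02	6.3700e+02
1.2849e-02	6.2871e+02
1.3477e-02	6.2013e+02
1.4136e-02	6.1125e+02
1.4827e-02	6.0207e+02
1.5552e-02	5.9259e+02
1.6312e-02	5.8280e+02
1.7109e-02	5.7271e+02
1.7946e-02	5.6231e+02
1.8823e-02	5.5160e+02
1.9743e-02	5.4060e+02
2.0709e-02	5.2929e+02
2.1721e-02	5.1769e+02
2.2783e-02	5.0580e+02
2.3897e-02	4.9363e+02
2.5065e-02	4.8119e+02
2.6290e-02	4.6848e+02
2.7575e-02	4.5551e+02
2.8923e-02	4.4231e+02
3.0337e-02	4.2888e+02
3.1820e-02	4.1523e+02
3.3376e-02	4.0139e+02
3.5008e-02	3.8738e+02
3.6719e-02	3.7321e+02
3.8514e-02	3.5891e+02
4.0397e-02	3.4452e+02
4.2372e-02	3.3005e+02
4.4443e-02	3.1553e+02
4.6616e-02	3.0100e+02
4.8894e-02	2.8650e+02
5.1285e-02	2.7205e+02
5.3792e-02	2.5769e+02
5.6422e-02	2.4346e+02
5.9180e-02	2.2939e+02
6.2073e-02	2.1553e+02
6.5107e-02	2.0191e+02
6.8290e-02	1.8857e+02
7.1629e-02	1.7555e+02
7.5130e-02	1.6288e+02
7.8803e-02	1.5060e+02
8.2655e-02	1.3875e+02
8.6696e-02	1.2734e+02
9.0934e-02	1.1642e+02
9.5380e-02	1.0601e+02
1.0004e-01	9.6134e+01
1.0493e-01	8.6804e+01
1.1006e-01	7.8038e+01
1.1544e-01	6.9847e+01
1.2109e-01	6.2235e+01
1.2701e-01	5.5204e+01
1.3322e-01	4.8750e+01
1.3973e-01	4.2865e+01
1.4656e-01	3.7535e+01
1.5372e-01	3.2743e+01
1.6124e-01	2.8466e+01
1.6912e-01	2.4680e+01
1.7739e-01	2.1356e+01
1.8606e-01	1.8463e+01
1.9516e-01	1.5967e+01
2.0470e-01	1.3836e+01
2.1470e-01	1.2031e+01
2.2520e-01	1.0519e+01
2.3621e-01	9.2618e+00
2.4776e-01	8.2261e+00
2.5987e-01	7.3786e+00
2.7257e-01	6.6885e+00
2.8590e-01	6.1272e+00
2.9987e-01	5.6688e+00
3.1453e-01	5.2903e+00
3.2991e-01	4.9716e+00
3.4604e-01	4.6956e+00
3.6295e-01	4.4485e+00
3.8070e-01	4.2192e+00
3.9931e-01	3.9993e+00
4.1883e-01	3.7829e+00
4.3930e-01	3.5662e+00
4.6078e-01	3.3468e+00
4.8330e-01	3.1242e+00
5.0693e-01	2.8986e+00
5.3171e-01	2.6714e+00
5.5771e-01	2.4444e+00
5.8497e-01	2.2199e+00
6.1357e-01	2.0003e+00
6.4356e-01	1.7880e+00
6.7502e-01	1.5852e+00
7.0802e-01	1.3937e+00
7.4263e-01	1.2149e+00
7.7894e-01	1.0497e+00
8.1702e-01	8.9883e-01
8.5696e-01	7.6246e-01
8.9885e-01	6.4060e-01
9.4279e-01	5.3296e-01
9.8888e-01	4.3902e-01
1.0372e+00	3.5805e-01
1.0879e+00	2.8913e-01
1.1411e+00	2.3117e-01
1.1969e+00	1.8302e-01
1.2554e+00	1.4347e-01
1.3168e+00	1.1135e-01
1.3812e+00	8.5557e-02
1.4487e+00	6.5094e-02
1.5195e+00	4.9067e-02
1.5938e+00	3.6695e-02
1.6717e+00	2.7290e-02
1.7534e+00	2.0257e-02
1.8391e+00	1.5082e-02
1.9290e+00	1.1332e-02
2.0233e+00	8.6500e-03
2.1223e+00	6.7502e-03
2.2260e+00	5.4115e-03
2.3348e+00	4.4675e-03
2.4490e+00	3.7960e-03
2.5687e+00	3.3086e-03
2.6943e+00	2.9425e-03
2.8260e+00	2.6536e-03
2.9641e+00	2.4114e-03
3.1090e+00	2.1960e-03
3.2610e+00	1.9952e-03
3.4204e+00	1.8024e-03
3.5876e+00	1.6150e-03
3.7630e+00	1.4329e-03
3.9470e+00	1.2572e-03
4.1399e+00	1.0899e-03
4.3423e+00	9.3298e-04
4.5546e+00	7.8809e-04
4.7773e+00	6.5656e-04
5.0108e+00	5.3919e-04
5.2558e+00	4.3624e-04
5.5127e+00	3.4749e-04
5.7822e+00	2.7234e-04
6.0649e+00	2.0985e-04
6.3614e+00	1.5884e-04
6.6723e+00	1.1802e-04
6.9985e+00	8.5993e-05
7.3407e+00	6.1402e-05
7.6995e+00	4.2931e-05
8.0759e+00	2.9371e-05
8.4707e+00	1.9647e-05
8.8848e+00	1.2840e-05
9.3192e+00	8.1904e-06
9.7747e+00	5.0917e-06
1.0253e+01	3.0788e-06
1.0754e+01	1.8055e-06
1.1280e+01	1.0230e-06
1.1831e+01	5.5721e-07
1.2409e+01	2.9006e-07
1.3016e+01	1.4330e-07
1.3652e+01	6.6661e-08
1.4320e+01	2.8954e-08
1.5020e+01	1.1635e-08
1.5754e+01	4.2848e-09
1.6524e+01	1.4313e-09
1.7332e+01	4.2906e-10
1.8179e+01	1.1410e-10
1.9068e+01	2.6582e-11
2.0000e+01	5.3535e-12
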