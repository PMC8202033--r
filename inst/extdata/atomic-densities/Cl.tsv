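# element	Cl
# Z	17
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-459.336522
r_bohr	rho_e_bohr3
1.5000e-03	3.0624e+03
1.5733e-03	3.0544e+03
1.6502e-03	3.0461e+03
1.7309e-03	3.0374e+03
1.8155e-03	3.0282e+03
1.9043e-03	3.0186e+03
1.9974e-03	3.0086e+03
2.0950e-03	2.9981e+03
2.1974e-03	2.9873e+03
2.3049e-03	2.9761e+03
2.4175e-03	2.9644e+03
2.5357e-03	2.9524e+03
2.6597e-03	2.9399e+03
2.7897e-03	2.9269e+03
2.9261e-03	2.9135e+03
3.0691e-03	2.8995e+03
3.2192e-03	2.8850e+03
3.3765e-03	2.8698e+03
3.5416e-03	2.8540e+03
3.7148e-03	2.8375e+03
3.8964e-03	2.8203e+03
4.0868e-03	2.8023e+03
4.2866e-03	2.7834e+03
4.4962e-03	2.7637e+03
4.7160e-03	2.7432e+03
4.9465e-03	2.7217e+03
5.1883e-03	2.6994e+03
5.4420e-03	2.6761e+03
5.7080e-03	2.6519e+03
5.9871e-03	2.6268e+03
6.2797e-03	2.6007e+03
6.5867e-03	2.5737e+03
6.9087e-03	2.5457e+03
7.2465e-03	2.5167e+03
7.6007e-03	2.4866e+03
7.9723e-03	2.4555e+03
8.3620e-03	2.4233e+03
8.7708e-03	2.3900e+03
9.1996e-03	2.3555e+03
9.6493e-03	2.3199e+03
1.0121e-02	2.2832e+03
1.0616e-02	2.2452e+03
1.1135e-02	2.2061e+03
1.1679e-02	2.1658e+03
1.2250e-02	2.1243e+03
1.2849e-02	2.0816e+03
1.3477e-02	2.0377e+03
1.4136e-02	1.9928e+03
1.4827e-02	1.9467e+03
1.5552e-02	1.8995e+03
1.6312e-02	1.8512e+03
1.7109e-02	1.8020e+03
1.7946e-02	1.7517e+03
1.8823e-02	1.7006e+03
1.9743e-02	1.6485e+03
2.0709e-02	1.5957e+03
2.1721e-02	1.5421e+03
2.2783e-02	1.4879e+03
2.3897e-02	1.4331e+03
2.5065e-02	1.3778e+03
2.6290e-02	1.3221e+03
2.7575e-02	1.2662e+03
2.8923e-02	1.2101e+03
3.0337e-02	1.1540e+03
3.1820e-02	1.0980e+03
3.3376e-02	1.0423e+03
3.5008e-02	9.8688e+02
3.6719e-02	9.3204e+02
3.8514e-02	8.7786e+02
4.0397e-02	8.2452e+02
4.2372e-02	7.7215e+02
4.4443e-02	7.2090e+02
4.6616e-02	6.7093e+02
4.8894e-02	6.2237e+02
5.1285e-02	5.7537e+02
5.3792e-02	5.3003e+02
5.6422e-02	4.8650e+02
5.9180e-02	4.4488e+02
6.2073e-02	4.0527e+02
6.5107e-02	3.6775e+02
6.8290e-02	3.3240e+02
7.1629e-02	2.9927e+02
7.5130e-02	2.6839e+02
7.8803e-02	2.3978e+02
8.2655e-02	2.1342e+02
8.6696e-02	1.8931e+02
9.0934e-02	1.6740e+02
9.5380e-02	1.4763e+02
1.0004e-01	1.2993e+02
1.0493e-01	1.1421e+02
1.1006e-01	1.0035e+02
1.1544e-01	8.8238e+01
1.2109e-01	7.7741e+01
1.2701e-01	6.8720e+01
1.3322e-01	6.1031e+01
1.3973e-01	5.4529e+01
1.4656e-01	4.9069e+01
1.5372e-01	4.4508e+01
1.6124e-01	4.0708e+01
1.6912e-01	3.7539e+01
1.7739e-01	3.4880e+01
1.8606e-01	3.2621e+01
1.9516e-01	3.0666e+01
2.0470e-01	2.8929e+01
2.1470e-01	2.7343e+01
2.2520e-01	2.5848e+01
2.3621e-01	2.4401e+01
2.4776e-01	2.2969e+01
2.5987e-01	2.1531e+01
2.7257e-01	2.0076e+01
2.8590e-01	1.8603e+01
2.9987e-01	1.7116e+01
3.1453e-01	1.5628e+01
3.2991e-01	1.4150e+01
3.4604e-01	1.2700e+01
3.6295e-01	1.1293e+01
3.8070e-01	9.9428e+00
3.9931e-01	8.6637e+00
4.1883e-01	7.4675e+00
4.3930e-01	6.3643e+00
4.6078e-01	5.3618e+00
4.8330e-01	4.4651e+00
5.0693e-01	3.6765e+00
5.3171e-01	2.9950e+00
5.5771e-01	2.4164e+00
5.8497e-01	1.9339e+00
6.1357e-01	1.5390e+00
6.4356e-01	1.2215e+00
6.7502e-01	9.7106e-01
7.0802e-01	7.7741e-01
7.4263e-01	6.3084e-01
7.7894e-01	5.2243e-01
8.1702e-01	4.4414e-01
8.5696e-01	3.8880e-01
8.9885e-01	3.5018e-01
9.4279e-01	3.2297e-01
9.8888e-01	3.0288e-01
1.0372e+00	2.8661e-01
1.0879e+00	2.7185e-01
1.1411e+00	2.5709e-01
1.1969e+00	2.4155e-01
1.2554e+00	2.2494e-01
1.3168e+00	2.0729e-01
1.3812e+00	1.8887e-01
1.4487e+00	1.7003e-01
1.5195e+00	1.5116e-01
1.5938e+00	1.3267e-01
1.6717e+00	1.1490e-01
1.7534e+00	9.8186e-02
1.8391e+00	8.2774e-02
1.9290e+00	6.8846e-02
2.0233e+00	5.6505e-02
2.1223e+00	4.5781e-02
2.2260e+00	3.6633e-02
2.3348e+00	2.8966e-02
2.4490e+00	2.2643e-02
2.5687e+00	1.7506e-02
2.6943e+00	1.3387e-02
2.8260e+00	1.0122e-02
2.9641e+00	7.5641e-03
3.1090e+00	5.5802e-03
3.2610e+00	4.0592e-03
3.4204e+00	2.9082e-03
3.5876e+00	2.0504e-03
3.7630e+00	1.4221e-03
3.9470e+00	9.7063e-04
4.1399e+00	6.5275e-04
4.3423e+00	4.3320e-04
4.5546e+00	2.8417e-04
4.7773e+00	1.8443e-04
5.0108e+00	1.1838e-04
5.2558e+00	7.4984e-05
5.5127e+00	4.6686e-05
5.7822e+00	2.8416e-05
6.0649e+00	1.6804e-05
6.3614e+00	9.5977e-06
6.6723e+00	5.2704e-06
6.9985e+00	2.7765e-06
7.3407e+00	1.4053e-06
7.6995e+00	6.8751e-07
8.0759e+00	3.2875e-07
8.4707e+00	1.5598e-07
8.8848e+00	7.4542e-08
9.3192e+00	3.6206e-08
9.7747e+00	1.7842e-08
1.0253e+01	8.8086e-09
1.0754e+01	4.2750e-09
1.1280e+01	1.9979e-09
1.1831e+01	8.8229e-10
1.2409e+01	3.6224e-10
1.3016e+01	1.3645e-10
1.3652e+01	4.6663e-11
1.4320e+01	1.4376e-11
1.5020e+01	3.9745e-12
1.5754e+01	9.8800e-13
1.6524e+01	2.2322e-13
1.7332e+01	4.6777e-14
1.8179e+01	9.3033e-15
1.9068e+01	1.7713e-15
2.0000e+01	3.1691e-16
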