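# element	Ca
# Z	20
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-676.748340
r_bohr	rho_e_bohr3
1.5000e-03	5.0129e+03
1.5733e-03	4.9974e+03
1.6502e-03	4.9813e+03
1.7309e-03	4.9644e+03
1.8155e-03	4.9469e+03
1.9043e-03	4.9288e+03
1.9974e-03	4.9099e+03
2.0950e-03	4.8904e+03
2.1974e-03	4.8701e+03
2.3049e-03	4.8491e+03
2.4175e-03	4.8274e+03
2.5357e-03	4.8048e+03
2.6597e-03	4.7813e+03
2.7897e-03	4.7569e+03
2.9261e-03	4.7315e+03
3.0691e-03	4.7049e+03
3.2192e-03	4.6772e+03
3.3765e-03	4.6482e+03
3.5416e-03	4.6179e+03
3.7148e-03	4.5862e+03
3.8964e-03	4.5531e+03
4.0868e-03	4.5185e+03
4.2866e-03	4.4825e+03
4.4962e-03	4.4450e+03
4.7160e-03	4.4059e+03
4.9465e-03	4.3654e+03
5.1883e-03	4.3232e+03
5.4420e-03	4.2795e+03
5.7080e-03	4.2341e+03
5.9871e-03	4.1871e+03
6.2797e-03	4.1384e+03
6.5867e-03	4.0880e+03
6.9087e-03	4.0359e+03
7.2465e-03	3.9819e+03
7.6007e-03	3.9261e+03
7.9723e-03	3.8684e+03
8.3620e-03	3.8088e+03
8.7708e-03	3.7472e+03
9.1996e-03	3.6837e+03
9.6493e-03	3.6183e+03
1.0121e-02	3.5509e+03
1.0616e-02	3.4815e+03
1.1135e-02	3.4102e+03
1.1679e-02	3.3370e+03
1.2250e-02	3.2619e+03
1.2849e-02	3.1850e+03
1.3477e-02	3.1063e+03
1.4136e-02	3.0258e+03
1.4827e-02	2.9438e+03
1.5552e-02	2.8601e+03
1.6312e-02	2.7749e+03
1.7109e-02	2.6884e+03
1.7946e-02	2.6005e+03
1.8823e-02	2.5115e+03
1.9743e-02	2.4215e+03
2.0709e-02	2.3306e+03
2.1721e-02	2.2390e+03
2.2783e-02	2.1468e+03
2.3897e-02	2.0543e+03
2.5065e-02	1.9616e+03
2.6290e-02	1.8690e+03
2.7575e-02	1.7766e+03
2.8923e-02	1.6848e+03
3.0337e-02	1.5936e+03
3.1820e-02	1.5035e+03
3.3376e-02	1.4146e+03
3.5008e-02	1.3271e+03
3.6719e-02	1.2414e+03
3.8514e-02	1.1576e+03
4.0397e-02	1.0761e+03
4.2372e-02	9.9703e+02
4.4443e-02	9.2062e+02
4.6616e-02	8.4708e+02
4.8894e-02	7.7661e+02
5.1285e-02	7.0938e+02
5.3792e-02	6.4555e+02
5.6422e-02	5.8525e+02
5.9180e-02	5.2859e+02
6.2073e-02	4.7563e+02
6.5107e-02	4.2643e+02
6.8290e-02	3.8098e+02
7.1629e-02	3.3926e+02
7.5130e-02	3.0123e+02
7.8803e-02	2.6679e+02
8.2655e-02	2.3584e+02
8.6696e-02	2.0824e+02
9.0934e-02	1.8382e+02
9.5380e-02	1.6238e+02
1.0004e-01	1.4373e+02
1.0493e-01	1.2762e+02
1.1006e-01	1.1383e+02
1.1544e-01	1.0210e+02
1.2109e-01	9.2185e+01
1.2701e-01	8.3849e+01
1.3322e-01	7.6854e+01
1.3973e-01	7.0975e+01
1.4656e-01	6.6002e+01
1.5372e-01	6.1743e+01
1.6124e-01	5.8027e+01
1.6912e-01	5.4706e+01
1.7739e-01	5.1653e+01
1.8606e-01	4.8768e+01
1.9516e-01	4.5971e+01
2.0470e-01	4.3203e+01
2.1470e-01	4.0426e+01
2.2520e-01	3.7619e+01
2.3621e-01	3.4777e+01
2.4776e-01	3.1911e+01
2.5987e-01	2.9040e+01
2.7257e-01	2.6194e+01
2.8590e-01	2.3407e+01
2.9987e-01	2.0711e+01
3.1453e-01	1.8139e+01
3.2991e-01	1.5718e+01
3.4604e-01	1.3471e+01
3.6295e-01	1.1414e+01
3.8070e-01	9.5597e+00
3.9931e-01	7.9146e+00
4.1883e-01	6.4807e+00
4.3930e-01	5.2548e+00
4.6078e-01	4.2288e+00
4.8330e-01	3.3895e+00
5.0693e-01	2.7193e+00
5.3171e-01	2.1974e+00
5.5771e-01	1.8013e+00
5.8497e-01	1.5080e+00
6.1357e-01	1.2959e+00
6.4356e-01	1.1454e+00
6.7502e-01	1.0396e+00
7.0802e-01	9.6457e-01
7.4263e-01	9.0900e-01
7.7894e-01	8.6408e-01
8.1702e-01	8.2317e-01
8.5696e-01	7.8158e-01
8.9885e-01	7.3644e-01
9.4279e-01	6.8641e-01
9.8888e-01	6.3152e-01
1.0372e+00	5.7279e-01
1.0879e+00	5.1183e-01
1.1411e+00	4.5053e-01
1.1969e+00	3.9072e-01
1.2554e+00	3.3394e-01
1.3168e+00	2.8137e-01
1.3812e+00	2.3378e-01
1.4487e+00	1.9157e-01
1.5195e+00	1.5483e-01
1.5938e+00	1.2342e-01
1.6717e+00	9.7043e-02
1.7534e+00	7.5298e-02
1.8391e+00	5.7718e-02
1.9290e+00	4.3798e-02
2.0233e+00	3.3024e-02
2.1223e+00	2.4882e-02
2.2260e+00	1.8877e-02
2.3348e+00	1.4548e-02
2.4490e+00	1.1486e-02
2.5687e+00	9.3420e-03
2.6943e+00	7.8332e-03
2.8260e+00	6.7448e-03
2.9641e+00	5.9219e-03
3.1090e+00	5.2593e-03
3.2610e+00	4.6907e-03
3.4204e+00	4.1772e-03
3.5876e+00	3.6987e-03
3.7630e+00	3.2470e-03
3.9470e+00	2.8202e-03
4.1399e+00	2.4200e-03
4.3423e+00	2.0495e-03
4.5546e+00	1.7115e-03
4.7773e+00	1.4082e-03
5.0108e+00	1.1409e-03
5.2558e+00	9.0946e-04
5.5127e+00	7.1281e-04
5.7822e+00	5.4889e-04
6.0649e+00	4.1491e-04
6.3614e+00	3.0765e-04
6.6723e+00	2.2360e-04
6.9985e+00	1.5920e-04
7.3407e+00	1.1099e-04
7.6995e+00	7.5757e-05
8.0759e+00	5.0620e-05
8.4707e+00	3.3116e-05
8.8848e+00	2.1211e-05
9.3192e+00	1.3297e-05
9.7747e+00	8.1526e-06
1.0253e+01	4.8795e-06
1.0754e+01	2.8426e-06
1.1280e+01	1.6051e-06
1.1831e+01	8.7351e-07
1.2409e+01	4.5511e-07
1.3016e+01	2.2525e-07
1.3652e+01	1.0502e-07
1.4320e+01	4.5711e-08
1.5020e+01	1.8402e-08
1.5754e+01	6.7854e-09
1.6524e+01	2.2686e-09
1.7332e+01	6.8042e-10
1.8179e+01	1.8099e-10
1.9068e+01	4.2174e-11
2.0000e+01	8.4943e-12
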