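# element	Mg
# Z	12
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-199.614278
r_bohr	rho_e_bohr3
1.5000e-03	1.0558e+03
1.5733e-03	1.0541e+03
1.6502e-03	1.0523e+03
1.7309e-03	1.0503e+03
1.8155e-03	1.0482e+03
1.9043e-03	1.0460e+03
1.9974e-03	1.0436e+03
2.0950e-03	1.0411e+03
2.1974e-03	1.0385e+03
2.3049e-03	1.0357e+03
2.4175e-03	1.0327e+03
2.5357e-03	1.0297e+03
2.6597e-03	1.0264e+03
2.7897e-03	1.0231e+03
2.9261e-03	1.0196e+03
3.0691e-03	1.0160e+03
3.2192e-03	1.0122e+03
3.3765e-03	1.0083e+03
3.5416e-03	1.0042e+03
3.7148e-03	1.0000e+03
3.8964e-03	9.9570e+02
4.0868e-03	9.9119e+02
4.2866e-03	9.8651e+02
4.4962e-03	9.8164e+02
4.7160e-03	9.7656e+02
4.9465e-03	9.7127e+02
5.1883e-03	9.6574e+02
5.4420e-03	9.5996e+02
5.7080e-03	9.5391e+02
5.9871e-03	9.4759e+02
6.2797e-03	9.4098e+02
6.5867e-03	9.3408e+02
6.9087e-03	9.2687e+02
7.2465e-03	9.1937e+02
7.6007e-03	9.1156e+02
7.9723e-03	9.0343e+02
8.3620e-03	8.9500e+02
8.7708e-03	8.8624e+02
9.1996e-03	8.7717e+02
9.6493e-03	8.6776e+02
1.0121e-02	8.5801e+02
1.0616e-02	8.4792e+02
1.1135e-02	8.3747e+02
1.1679e-02	8.2665e+02
1.2250e-02	8.1546e+02
1.2849e-02	8.0388e+02
1.3477e-02	7.9191e+02
1.4136e-02	7.7954e+02
1.4827e-02	7.6677e+02
1.5552e-02	7.5360e+02
1.6312e-02	7.4002e+02
1.7109e-02	7.2605e+02
1.7946e-02	7.1168e+02
1.8823e-02	6.9691e+02
1.9743e-02	6.8176e+02
2.0709e-02	6.6622e+02
2.1721e-02	6.5031e+02
2.2783e-02	6.3405e+02
2.3897e-02	6.1743e+02
2.5065e-02	6.0048e+02
2.6290e-02	5.8320e+02
2.7575e-02	5.6563e+02
2.8923e-02	5.4777e+02
3.0337e-02	5.2965e+02
3.1820e-02	5.1130e+02
3.3376e-02	4.9274e+02
3.5008e-02	4.7401e+02
3.6719e-02	4.5514e+02
3.8514e-02	4.3617e+02
4.0397e-02	4.1713e+02
4.2372e-02	3.9807e+02
4.4443e-02	3.7903e+02
4.6616e-02	3.6005e+02
4.8894e-02	3.4119e+02
5.1285e-02	3.2249e+02
5.3792e-02	3.0399e+02
5.6422e-02	2.8576e+02
5.9180e-02	2.6784e+02
6.2073e-02	2.5028e+02
6.5107e-02	2.3313e+02
6.8290e-02	2.1643e+02
7.1629e-02	2.0024e+02
7.5130e-02	1.8460e+02
7.8803e-02	1.6955e+02
8.2655e-02	1.5513e+02
8.6696e-02	1.4137e+02
9.0934e-02	1.2831e+02
9.5380e-02	1.1597e+02
1.0004e-01	1.0436e+02
1.0493e-01	9.3516e+01
1.1006e-01	8.3430e+01
1.1544e-01	7.4108e+01
1.2109e-01	6.5546e+01
1.2701e-01	5.7735e+01
1.3322e-01	5.0656e+01
1.3973e-01	4.4288e+01
1.4656e-01	3.8603e+01
1.5372e-01	3.3566e+01
1.6124e-01	2.9141e+01
1.6912e-01	2.5288e+01
1.7739e-01	2.1962e+01
1.8606e-01	1.9118e+01
1.9516e-01	1.6708e+01
2.0470e-01	1.4685e+01
2.1470e-01	1.3002e+01
2.2520e-01	1.1612e+01
2.3621e-01	1.0471e+01
2.4776e-01	9.5381e+00
2.5987e-01	8.7746e+00
2.7257e-01	8.1461e+00
2.8590e-01	7.6218e+00
2.9987e-01	7.1751e+00
3.1453e-01	6.7831e+00
3.2991e-01	6.4273e+00
3.4604e-01	6.0930e+00
3.6295e-01	5.7692e+00
3.8070e-01	5.4483e+00
3.9931e-01	5.1255e+00
4.1883e-01	4.7985e+00
4.3930e-01	4.4667e+00
4.6078e-01	4.1312e+00
4.8330e-01	3.7939e+00
5.0693e-01	3.4578e+00
5.3171e-01	3.1263e+00
5.5771e-01	2.8031e+00
5.8497e-01	2.4918e+00
6.1357e-01	2.1957e+00
6.4356e-01	1.9175e+00
6.7502e-01	1.6592e+00
7.0802e-01	1.4223e+00
7.4263e-01	1.2076e+00
7.7894e-01	1.0151e+00
8.1702e-01	8.4451e-01
8.5696e-01	6.9522e-01
8.9885e-01	5.6619e-01
9.4279e-01	4.5616e-01
9.8888e-01	3.6365e-01
1.0372e+00	2.8699e-01
1.0879e+00	2.2440e-01
1.1411e+00	1.7403e-01
1.1969e+00	1.3407e-01
1.2554e+00	1.0279e-01
1.3168e+00	7.8648e-02
1.3812e+00	6.0269e-02
1.4487e+00	4.6480e-02
1.5195e+00	3.6292e-02
1.5938e+00	2.8878e-02
1.6717e+00	2.3554e-02
1.7534e+00	1.9759e-02
1.8391e+00	1.7045e-02
1.9290e+00	1.5064e-02
2.0233e+00	1.3557e-02
2.1223e+00	1.2338e-02
2.2260e+00	1.1284e-02
2.3348e+00	1.0320e-02
2.4490e+00	9.4002e-03
2.5687e+00	8.5060e-03
2.6943e+00	7.6314e-03
2.8260e+00	6.7794e-03
2.9641e+00	5.9575e-03
3.1090e+00	5.1750e-03
3.2610e+00	4.4411e-03
3.4204e+00	3.7634e-03
3.5876e+00	3.1477e-03
3.7630e+00	2.5974e-03
3.9470e+00	2.1135e-03
4.1399e+00	1.6950e-03
4.3423e+00	1.3392e-03
4.5546e+00	1.0418e-03
4.7773e+00	7.9759e-04
5.0108e+00	6.0066e-04
5.2558e+00	4.4475e-04
5.5127e+00	3.2359e-04
5.7822e+00	2.3121e-04
6.0649e+00	1.6209e-04
6.3614e+00	1.1140e-04
6.6723e+00	7.4955e-05
6.9985e+00	4.9311e-05
7.3407e+00	3.1670e-05
7.6995e+00	1.9829e-05
8.0759e+00	1.2087e-05
8.4707e+00	7.1684e-06
8.8848e+00	4.1352e-06
9.3192e+00	2.3218e-06
9.7747e+00	1.2704e-06
1.0253e+01	6.7852e-07
1.0754e+01	3.5424e-07
1.1280e+01	1.8083e-07
1.1831e+01	9.0104e-08
1.2409e+01	4.3641e-08
1.3016e+01	2.0403e-08
1.3652e+01	9.1216e-09
1.4320e+01	3.8565e-09
1.5020e+01	1.5234e-09
1.5754e+01	5.5526e-10
1.6524e+01	1.8442e-10
1.7332e+01	5.5118e-11
1.8179e+01	1.4636e-11
1.9068e+01	3.4078e-12
2.0000e+01	6.8613e-13
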