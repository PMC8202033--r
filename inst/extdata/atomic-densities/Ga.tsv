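# element	Ga
# Z	31
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1922.979091
r_bohr	rho_e_bohr3
1.5000e-03	1.8579e+04
1.5733e-03	1.8495e+04
1.6502e-03	1.8407e+04
1.7309e-03	1.8316e+04
1.8155e-03	1.8222e+04
1.9043e-03	1.8124e+04
1.9974e-03	1.8021e+04
2.0950e-03	1.7914e+04
2.1974e-03	1.7802e+04
2.3049e-03	1.7685e+04
2.4175e-03	1.7562e+04
2.5357e-03	1.7434e+04
2.6597e-03	1.7301e+04
2.7897e-03	1.7162e+04
2.9261e-03	1.7017e+04
3.0691e-03	1.6867e+04
3.2192e-03	1.6710e+04
3.3765e-03	1.6547e+04
3.5416e-03	1.6378e+04
3.7148e-03	1.6203e+04
3.8964e-03	1.6021e+04
4.0868e-03	1.5833e+04
4.2866e-03	1.5639e+04
4.4962e-03	1.5437e+04
4.7160e-03	1.5229e+04
4.9465e-03	1.5013e+04
5.1883e-03	1.4790e+04
5.4420e-03	1.4560e+04
5.7080e-03	1.4323e+04
5.9871e-03	1.4078e+04
6.2797e-03	1.3826e+04
6.5867e-03	1.3566e+04
6.9087e-03	1.3298e+04
7.2465e-03	1.3024e+04
7.6007e-03	1.2742e+04
7.9723e-03	1.2452e+04
8.3620e-03	1.2156e+04
8.7708e-03	1.1853e+04
9.1996e-03	1.1543e+04
9.6493e-03	1.1227e+04
1.0121e-02	1.0905e+04
1.0616e-02	1.0577e+04
1.1135e-02	1.0244e+04
1.1679e-02	9.9063e+03
1.2250e-02	9.5642e+03
1.2849e-02	9.2182e+03
1.3477e-02	8.8690e+03
1.4136e-02	8.5172e+03
1.4827e-02	8.1635e+03
1.5552e-02	7.8086e+03
1.6312e-02	7.4533e+03
1.7109e-02	7.0984e+03
1.7946e-02	6.7448e+03
1.8823e-02	6.3934e+03
1.9743e-02	6.0450e+03
2.0709e-02	5.7006e+03
2.1721e-02	5.3612e+03
2.2783e-02	5.0276e+03
2.3897e-02	4.7009e+03
2.5065e-02	4.3821e+03
2.6290e-02	4.0720e+03
2.7575e-02	3.7717e+03
2.8923e-02	3.4818e+03
3.0337e-02	3.2034e+03
3.1820e-02	2.9370e+03
3.3376e-02	2.6832e+03
3.5008e-02	2.4427e+03
3.6719e-02	2.2160e+03
3.8514e-02	2.0033e+03
4.0397e-02	1.8049e+03
4.2372e-02	1.6211e+03
4.4443e-02	1.4517e+03
4.6616e-02	1.2968e+03
4.8894e-02	1.1559e+03
5.1285e-02	1.0287e+03
5.3792e-02	9.1478e+02
5.6422e-02	8.1341e+02
5.9180e-02	7.2394e+02
6.2073e-02	6.4558e+02
6.5107e-02	5.7750e+02
6.8290e-02	5.1879e+02
7.1629e-02	4.6852e+02
7.5130e-02	4.2571e+02
7.8803e-02	3.8939e+02
8.2655e-02	3.5860e+02
8.6696e-02	3.3241e+02
9.0934e-02	3.0994e+02
9.5380e-02	2.9042e+02
1.0004e-01	2.7311e+02
1.0493e-01	2.5740e+02
1.1006e-01	2.4276e+02
1.1544e-01	2.2878e+02
1.2109e-01	2.1513e+02
1.2701e-01	2.0160e+02
1.3322e-01	1.8806e+02
1.3973e-01	1.7444e+02
1.4656e-01	1.6075e+02
1.5372e-01	1.4705e+02
1.6124e-01	1.3344e+02
1.6912e-01	1.2004e+02
1.7739e-01	1.0700e+02
1.8606e-01	9.4483e+01
1.9516e-01	8.2642e+01
2.0470e-01	7.1629e+01
2.1470e-01	6.1567e+01
2.2520e-01	5.2545e+01
2.3621e-01	4.4608e+01
2.4776e-01	3.7756e+01
2.5987e-01	3.1951e+01
2.7257e-01	2.7121e+01
2.8590e-01	2.3172e+01
2.9987e-01	1.9998e+01
3.1453e-01	1.7489e+01
3.2991e-01	1.5535e+01
3.4604e-01	1.4031e+01
3.6295e-01	1.2876e+01
3.8070e-01	1.1975e+01
3.9931e-01	1.1244e+01
4.1883e-01	1.0608e+01
4.3930e-01	1.0010e+01
4.6078e-01	9.4091e+00
4.8330e-01	8.7827e+00
5.0693e-01	8.1245e+00
5.3171e-01	7.4406e+00
5.5771e-01	6.7447e+00
5.8497e-01	6.0529e+00
6.1357e-01	5.3807e+00
6.4356e-01	4.7402e+00
6.7502e-01	4.1391e+00
7.0802e-01	3.5816e+00
7.4263e-01	3.0689e+00
7.7894e-01	2.6009e+00
8.1702e-01	2.1768e+00
8.5696e-01	1.7965e+00
8.9885e-01	1.4600e+00
9.4279e-01	1.1678e+00
9.8888e-01	9.1964e-01
1.0372e+00	7.1427e-01
1.0879e+00	5.4896e-01
1.1411e+00	4.1955e-01
1.1969e+00	3.2080e-01
1.2554e+00	2.4700e-01
1.3168e+00	1.9255e-01
1.3812e+00	1.5248e-01
1.4487e+00	1.2266e-01
1.5195e+00	9.9955e-02
1.5938e+00	8.2162e-02
1.6717e+00	6.7825e-02
1.7534e+00	5.6058e-02
1.8391e+00	4.6340e-02
1.9290e+00	3.8340e-02
2.0233e+00	3.1805e-02
2.1223e+00	2.6499e-02
2.2260e+00	2.2187e-02
2.3348e+00	1.8655e-02
2.4490e+00	1.5718e-02
2.5687e+00	1.3237e-02
2.6943e+00	1.1112e-02
2.8260e+00	9.2785e-03
2.9641e+00	7.6948e-03
3.1090e+00	6.3321e-03
3.2610e+00	5.1685e-03
3.4204e+00	4.1848e-03
3.5876e+00	3.3625e-03
3.7630e+00	2.6830e-03
3.9470e+00	2.1279e-03
4.1399e+00	1.6787e-03
4.3423e+00	1.3182e-03
4.5546e+00	1.0309e-03
4.7773e+00	8.0293e-04
5.0108e+00	6.2272e-04
5.2558e+00	4.8067e-04
5.5127e+00	3.6900e-04
5.7822e+00	2.8150e-04
6.0649e+00	2.1316e-04
6.3614e+00	1.6002e-04
6.6723e+00	1.1889e-04
6.9985e+00	8.7223e-05
7.3407e+00	6.3005e-05
7.6995e+00	4.4639e-05
8.0759e+00	3.0878e-05
8.4707e+00	2.0738e-05
8.8848e+00	1.3441e-05
9.3192e+00	8.3515e-06
9.7747e+00	4.9394e-06
1.0253e+01	2.7606e-06
1.0754e+01	1.4471e-06
1.1280e+01	7.0592e-07
1.1831e+01	3.1789e-07
1.2409e+01	1.3101e-07
1.3016e+01	4.8963e-08
1.3652e+01	1.6430e-08
1.4320e+01	4.8974e-09
1.5020e+01	1.2818e-09
1.5754e+01	2.9090e-10
1.6524e+01	5.6514e-11
1.7332e+01	9.2800e-12
1.8179e+01	1.2753e-12
1.9068e+01	1.4651e-13
2.0000e+01	1.4373e-14
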