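# element	Mn
# Z	25
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-1149.810197
r_bohr	rho_e_bohr3
1.5000e-03	9.7964e+03
1.5733e-03	9.7594e+03
1.6502e-03	9.7210e+03
1.7309e-03	9.6812e+03
1.8155e-03	9.6400e+03
1.9043e-03	9.5972e+03
1.9974e-03	9.5529e+03
2.0950e-03	9.5069e+03
2.1974e-03	9.4590e+03
2.3049e-03	9.4091e+03
2.4175e-03	9.3571e+03
2.5357e-03	9.3028e+03
2.6597e-03	9.2461e+03
2.7897e-03	9.1868e+03
2.9261e-03	9.1248e+03
3.0691e-03	9.0601e+03
3.2192e-03	8.9925e+03
3.3765e-03	8.9220e+03
3.5416e-03	8.8485e+03
3.7148e-03	8.7720e+03
3.8964e-03	8.6924e+03
4.0868e-03	8.6098e+03
4.2866e-03	8.5239e+03
4.4962e-03	8.4349e+03
4.7160e-03	8.3426e+03
4.9465e-03	8.2470e+03
5.1883e-03	8.1480e+03
5.4420e-03	8.0455e+03
5.7080e-03	7.9395e+03
5.9871e-03	7.8299e+03
6.2797e-03	7.7165e+03
6.5867e-03	7.5994e+03
6.9087e-03	7.4784e+03
7.2465e-03	7.3536e+03
7.6007e-03	7.2249e+03
7.9723e-03	7.0923e+03
8.3620e-03	6.9559e+03
8.7708e-03	6.8156e+03
9.1996e-03	6.6715e+03
9.6493e-03	6.5236e+03
1.0121e-02	6.3721e+03
1.0616e-02	6.2169e+03
1.1135e-02	6.0583e+03
1.1679e-02	5.8963e+03
1.2250e-02	5.7311e+03
1.2849e-02	5.5630e+03
1.3477e-02	5.3920e+03
1.4136e-02	5.2184e+03
1.4827e-02	5.0424e+03
1.5552e-02	4.8642e+03
1.6312e-02	4.6843e+03
1.7109e-02	4.5028e+03
1.7946e-02	4.3201e+03
1.8823e-02	4.1366e+03
1.9743e-02	3.9527e+03
2.0709e-02	3.7688e+03
2.1721e-02	3.5853e+03
2.2783e-02	3.4027e+03
2.3897e-02	3.2214e+03
2.5065e-02	3.0419e+03
2.6290e-02	2.8647e+03
2.7575e-02	2.6902e+03
2.8923e-02	2.5190e+03
3.0337e-02	2.3517e+03
3.1820e-02	2.1886e+03
3.3376e-02	2.0302e+03
3.5008e-02	1.8771e+03
3.6719e-02	1.7296e+03
3.8514e-02	1.5881e+03
4.0397e-02	1.4530e+03
4.2372e-02	1.3246e+03
4.4443e-02	1.2031e+03
4.6616e-02	1.0888e+03
4.8894e-02	9.8186e+02
5.1285e-02	8.8239e+02
5.3792e-02	7.9041e+02
5.6422e-02	7.0589e+02
5.9180e-02	6.2874e+02
6.2073e-02	5.5878e+02
6.5107e-02	4.9580e+02
6.8290e-02	4.3953e+02
7.1629e-02	3.8964e+02
7.5130e-02	3.4576e+02
7.8803e-02	3.0749e+02
8.2655e-02	2.7437e+02
8.6696e-02	2.4593e+02
9.0934e-02	2.2167e+02
9.5380e-02	2.0109e+02
1.0004e-01	1.8370e+02
1.0493e-01	1.6900e+02
1.1006e-01	1.5654e+02
1.1544e-01	1.4590e+02
1.2109e-01	1.3668e+02
1.2701e-01	1.2853e+02
1.3322e-01	1.2114e+02
1.3973e-01	1.1427e+02
1.4656e-01	1.0772e+02
1.5372e-01	1.0132e+02
1.6124e-01	9.4974e+01
1.6912e-01	8.8606e+01
1.7739e-01	8.2187e+01
1.8606e-01	7.5715e+01
1.9516e-01	6.9215e+01
2.0470e-01	6.2735e+01
2.1470e-01	5.6342e+01
2.2520e-01	5.0111e+01
2.3621e-01	4.4125e+01
2.4776e-01	3.8461e+01
2.5987e-01	3.3188e+01
2.7257e-01	2.8357e+01
2.8590e-01	2.4003e+01
2.9987e-01	2.0143e+01
3.1453e-01	1.6776e+01
3.2991e-01	1.3888e+01
3.4604e-01	1.1457e+01
3.6295e-01	9.4489e+00
3.8070e-01	7.8275e+00
3.9931e-01	6.5493e+00
4.1883e-01	5.5672e+00
4.3930e-01	4.8316e+00
4.6078e-01	4.2923e+00
4.8330e-01	3.9011e+00
5.0693e-01	3.6147e+00
5.3171e-01	3.3964e+00
5.5771e-01	3.2171e+00
5.8497e-01	3.0555e+00
6.1357e-01	2.8974e+00
6.4356e-01	2.7339e+00
6.7502e-01	2.5604e+00
7.0802e-01	2.3755e+00
7.4263e-01	2.1798e+00
7.7894e-01	1.9754e+00
8.1702e-01	1.7659e+00
8.5696e-01	1.5556e+00
8.9885e-01	1.3496e+00
9.4279e-01	1.1527e+00
9.8888e-01	9.6971e-01
1.0372e+00	8.0407e-01
1.0879e+00	6.5812e-01
1.1411e+00	5.3273e-01
1.1969e+00	4.2747e-01
1.2554e+00	3.4085e-01
1.3168e+00	2.7067e-01
1.3812e+00	2.1443e-01
1.4487e+00	1.6960e-01
1.5195e+00	1.3392e-01
1.5938e+00	1.0548e-01
1.6717e+00	8.2813e-02
1.7534e+00	6.4797e-02
1.8391e+00	5.0596e-02
1.9290e+00	3.9552e-02
2.0233e+00	3.1105e-02
2.1223e+00	2.4746e-02
2.2260e+00	2.0010e-02
2.3348e+00	1.6482e-02
2.4490e+00	1.3814e-02
2.5687e+00	1.1734e-02
2.6943e+00	1.0045e-02
2.8260e+00	8.6168e-03
2.9641e+00	7.3694e-03
3.1090e+00	6.2597e-03
3.2610e+00	5.2677e-03
3.4204e+00	4.3855e-03
3.5876e+00	3.6100e-03
3.7630e+00	2.9383e-03
3.9470e+00	2.3650e-03
4.1399e+00	1.8826e-03
4.3423e+00	1.4817e-03
4.5546e+00	1.1524e-03
4.7773e+00	8.8509e-04
5.0108e+00	6.7061e-04
5.2558e+00	5.0072e-04
5.5127e+00	3.6803e-04
5.7822e+00	2.6595e-04
6.0649e+00	1.8870e-04
6.3614e+00	1.3127e-04
6.6723e+00	8.9422e-05
6.9985e+00	5.9568e-05
7.3407e+00	3.8768e-05
7.6995e+00	2.4639e-05
8.0759e+00	1.5295e-05
8.4707e+00	9.2812e-06
8.8848e+00	5.5137e-06
9.3192e+00	3.2126e-06
9.7747e+00	1.8387e-06
1.0253e+01	1.0344e-06
1.0754e+01	5.7148e-07
1.1280e+01	3.0904e-07
1.1831e+01	1.6269e-07
1.2409e+01	8.2747e-08
1.3016e+01	4.0287e-08
1.3652e+01	1.8586e-08
1.4320e+01	8.0385e-09
1.5020e+01	3.2246e-09
1.5754e+01	1.1868e-09
1.6524e+01	3.9646e-10
1.7332e+01	1.1886e-10
1.8179e+01	3.1612e-11
1.9068e+01	7.3659e-12
2.0000e+01	1.4835e-12
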