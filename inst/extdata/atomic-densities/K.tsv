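# element	K
# Z	19
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-599.158171
r_bohr	rho_e_bohr3
1.5000e-03	4.2904e+03
1.5733e-03	4.2779e+03
1.6502e-03	4.2647e+03
1.7309e-03	4.2510e+03
1.8155e-03	4.2367e+03
1.9043e-03	4.2218e+03
1.9974e-03	4.2064e+03
2.0950e-03	4.1903e+03
2.1974e-03	4.1737e+03
2.3049e-03	4.1565e+03
2.4175e-03	4.1386e+03
2.5357e-03	4.1201e+03
2.6597e-03	4.1009e+03
2.7897e-03	4.0810e+03
2.9261e-03	4.0602e+03
3.0691e-03	4.0385e+03
3.2192e-03	4.0160e+03
3.3765e-03	3.9924e+03
3.5416e-03	3.9677e+03
3.7148e-03	3.9419e+03
3.8964e-03	3.9150e+03
4.0868e-03	3.8868e+03
4.2866e-03	3.8575e+03
4.4962e-03	3.8268e+03
4.7160e-03	3.7949e+03
4.9465e-03	3.7617e+03
5.1883e-03	3.7271e+03
5.4420e-03	3.6913e+03
5.7080e-03	3.6541e+03
5.9871e-03	3.6155e+03
6.2797e-03	3.5755e+03
6.5867e-03	3.5341e+03
6.9087e-03	3.4912e+03
7.2465e-03	3.4468e+03
7.6007e-03	3.4009e+03
7.9723e-03	3.3534e+03
8.3620e-03	3.3043e+03
8.7708e-03	3.2536e+03
9.1996e-03	3.2012e+03
9.6493e-03	3.1471e+03
1.0121e-02	3.0914e+03
1.0616e-02	3.0340e+03
1.1135e-02	2.9749e+03
1.1679e-02	2.9142e+03
1.2250e-02	2.8519e+03
1.2849e-02	2.7880e+03
1.3477e-02	2.7225e+03
1.4136e-02	2.6554e+03
1.4827e-02	2.5869e+03
1.5552e-02	2.5170e+03
1.6312e-02	2.4457e+03
1.7109e-02	2.3732e+03
1.7946e-02	2.2994e+03
1.8823e-02	2.2245e+03
1.9743e-02	2.1487e+03
2.0709e-02	2.0719e+03
2.1721e-02	1.9944e+03
2.2783e-02	1.9163e+03
2.3897e-02	1.8377e+03
2.5065e-02	1.7588e+03
2.6290e-02	1.6797e+03
2.7575e-02	1.6006e+03
2.8923e-02	1.5218e+03
3.0337e-02	1.4434e+03
3.1820e-02	1.3656e+03
3.3376e-02	1.2886e+03
3.5008e-02	1.2126e+03
3.6719e-02	1.1379e+03
3.8514e-02	1.0646e+03
4.0397e-02	9.9300e+02
4.2372e-02	9.2326e+02
4.4443e-02	8.5559e+02
4.6616e-02	7.9018e+02
4.8894e-02	7.2720e+02
5.1285e-02	6.6682e+02
5.3792e-02	6.0920e+02
5.6422e-02	5.5446e+02
5.9180e-02	5.0272e+02
6.2073e-02	4.5407e+02
6.5107e-02	4.0858e+02
6.8290e-02	3.6628e+02
7.1629e-02	3.2718e+02
7.5130e-02	2.9126e+02
7.8803e-02	2.5849e+02
8.2655e-02	2.2880e+02
8.6696e-02	2.0209e+02
9.0934e-02	1.7825e+02
9.5380e-02	1.5714e+02
1.0004e-01	1.3859e+02
1.0493e-01	1.2244e+02
1.1006e-01	1.0848e+02
1.1544e-01	9.6512e+01
1.2109e-01	8.6336e+01
1.2701e-01	7.7738e+01
1.3322e-01	7.0513e+01
1.3973e-01	6.4460e+01
1.4656e-01	5.9388e+01
1.5372e-01	5.5116e+01
1.6124e-01	5.1479e+01
1.6912e-01	4.8330e+01
1.7739e-01	4.5539e+01
1.8606e-01	4.2997e+01
1.9516e-01	4.0614e+01
2.0470e-01	3.8320e+01
2.1470e-01	3.6060e+01
2.2520e-01	3.3800e+01
2.3621e-01	3.1517e+01
2.4776e-01	2.9206e+01
2.5987e-01	2.6871e+01
2.7257e-01	2.4528e+01
2.8590e-01	2.2199e+01
2.9987e-01	1.9910e+01
3.1453e-01	1.7688e+01
3.2991e-01	1.5557e+01
3.4604e-01	1.3541e+01
3.6295e-01	1.1658e+01
3.8070e-01	9.9247e+00
3.9931e-01	8.3509e+00
4.1883e-01	6.9449e+00
4.3930e-01	5.7099e+00
4.6078e-01	4.6454e+00
4.8330e-01	3.7459e+00
5.0693e-01	3.0019e+00
5.3171e-01	2.4001e+00
5.5771e-01	1.9241e+00
5.8497e-01	1.5562e+00
6.1357e-01	1.2784e+00
6.4356e-01	1.0733e+00
6.7502e-01	9.2504e-01
7.0802e-01	8.1989e-01
7.4263e-01	7.4600e-01
7.7894e-01	6.9355e-01
8.1702e-01	6.5450e-01
8.5696e-01	6.2253e-01
8.9885e-01	5.9293e-01
9.4279e-01	5.6248e-01
9.8888e-01	5.2934e-01
1.0372e+00	4.9286e-01
1.0879e+00	4.5328e-01
1.1411e+00	4.1144e-01
1.1969e+00	3.6846e-01
1.2554e+00	3.2554e-01
1.3168e+00	2.8378e-01
1.3812e+00	2.4406e-01
1.4487e+00	2.0708e-01
1.5195e+00	1.7329e-01
1.5938e+00	1.4296e-01
1.6717e+00	1.1623e-01
1.7534e+00	9.3081e-02
1.8391e+00	7.3400e-02
1.9290e+00	5.6990e-02
2.0233e+00	4.3587e-02
2.1223e+00	3.2870e-02
2.2260e+00	2.4487e-02
2.3348e+00	1.8072e-02
2.4490e+00	1.3265e-02
2.5687e+00	9.7313e-03
2.6943e+00	7.1759e-03
2.8260e+00	5.3512e-03
2.9641e+00	4.0593e-03
3.1090e+00	3.1479e-03
3.2610e+00	2.5042e-03
3.4204e+00	2.0463e-03
3.5876e+00	1.7156e-03
3.7630e+00	1.4708e-03
3.9470e+00	1.2825e-03
4.1399e+00	1.1303e-03
4.3423e+00	1.0005e-03
4.5546e+00	8.8431e-04
4.7773e+00	7.7692e-04
5.0108e+00	6.7612e-04
5.2558e+00	5.8136e-04
5.5127e+00	4.9304e-04
5.7822e+00	4.1187e-04
6.0649e+00	3.3857e-04
6.3614e+00	2.7365e-04
6.6723e+00	2.1731e-04
6.9985e+00	1.6941e-04
7.3407e+00	1.2955e-04
7.6995e+00	9.7086e-05
8.0759e+00	7.1215e-05
8.4707e+00	5.1055e-05
8.8848e+00	3.5708e-05
9.3192e+00	2.4307e-05
9.7747e+00	1.6060e-05
1.0253e+01	1.0263e-05
1.0754e+01	6.3196e-06
1.1280e+01	3.7321e-06
1.1831e+01	2.1029e-06
1.2409e+01	1.1242e-06
1.3016e+01	5.6657e-07
1.3652e+01	2.6736e-07
1.4320e+01	1.1727e-07
1.5020e+01	4.7423e-08
1.5754e+01	1.7531e-08
1.6524e+01	5.8691e-09
1.7332e+01	1.7614e-09
1.8179e+01	4.6867e-10
1.9068e+01	1.0922e-10
2.0000e+01	2.1999e-11
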