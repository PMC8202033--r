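# element	Kr
# Z	36
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-2751.556712
r_bohr	rho_e_bohr3
1.5000e-03	2.8928e+04
1.5733e-03	2.8777e+04
1.6502e-03	2.8621e+04
1.7309e-03	2.8458e+04
1.8155e-03	2.8287e+04
1.9043e-03	2.8109e+04
1.9974e-03	2.7923e+04
2.0950e-03	2.7729e+04
2.1974e-03	2.7526e+04
2.3049e-03	2.7314e+04
2.4175e-03	2.7093e+04
2.5357e-03	2.6863e+04
2.6597e-03	2.6624e+04
2.7897e-03	2.6375e+04
2.9261e-03	2.6116e+04
3.0691e-03	2.5848e+04
3.2192e-03	2.5570e+04
3.3765e-03	2.5281e+04
3.5416e-03	2.4982e+04
3.7148e-03	2.4673e+04
3.8964e-03	2.4353e+04
4.0868e-03	2.4022e+04
4.2866e-03	2.3680e+04
4.4962e-03	2.3327e+04
4.7160e-03	2.2962e+04
4.9465e-03	2.2585e+04
5.1883e-03	2.2196e+04
5.4420e-03	2.1796e+04
5.7080e-03	2.1383e+04
5.9871e-03	2.0959e+04
6.2797e-03	2.0523e+04
6.5867e-03	2.0076e+04
6.9087e-03	1.9617e+04
7.2465e-03	1.9147e+04
7.6007e-03	1.8667e+04
7.9723e-03	1.8176e+04
8.3620e-03	1.7675e+04
8.7708e-03	1.7165e+04
9.1996e-03	1.6646e+04
9.6493e-03	1.6118e+04
1.0121e-02	1.5584e+04
1.0616e-02	1.5042e+04
1.1135e-02	1.4495e+04
1.1679e-02	1.3942e+04
1.2250e-02	1.3386e+04
1.2849e-02	1.2827e+04
1.3477e-02	1.2266e+04
1.4136e-02	1.1704e+04
1.4827e-02	1.1144e+04
1.5552e-02	1.0585e+04
1.6312e-02	1.0031e+04
1.7109e-02	9.4812e+03
1.7946e-02	8.9382e+03
1.8823e-02	8.4033e+03
1.9743e-02	7.8780e+03
2.0709e-02	7.3638e+03
2.1721e-02	6.8622e+03
2.2783e-02	6.3747e+03
2.3897e-02	5.9028e+03
2.5065e-02	5.4479e+03
2.6290e-02	5.0111e+03
2.7575e-02	4.5936e+03
2.8923e-02	4.1963e+03
3.0337e-02	3.8202e+03
3.1820e-02	3.4658e+03
3.3376e-02	3.1338e+03
3.5008e-02	2.8245e+03
3.6719e-02	2.5381e+03
3.8514e-02	2.2746e+03
4.0397e-02	2.0339e+03
4.2372e-02	1.8154e+03
4.4443e-02	1.6185e+03
4.6616e-02	1.4423e+03
4.8894e-02	1.2858e+03
5.1285e-02	1.1479e+03
5.3792e-02	1.0272e+03
5.6422e-02	9.2245e+02
5.9180e-02	8.3212e+02
6.2073e-02	7.5475e+02
6.5107e-02	6.8879e+02
6.8290e-02	6.3271e+02
7.1629e-02	5.8498e+02
7.5130e-02	5.4416e+02
7.8803e-02	5.0886e+02
8.2655e-02	4.7784e+02
8.6696e-02	4.4999e+02
9.0934e-02	4.2436e+02
9.5380e-02	4.0016e+02
1.0004e-01	3.7678e+02
1.0493e-01	3.5375e+02
1.1006e-01	3.3080e+02
1.1544e-01	3.0777e+02
1.2109e-01	2.8464e+02
1.2701e-01	2.6148e+02
1.3322e-01	2.3843e+02
1.3973e-01	2.1568e+02
1.4656e-01	1.9347e+02
1.5372e-01	1.7203e+02
1.6124e-01	1.5161e+02
1.6912e-01	1.3246e+02
1.7739e-01	1.1480e+02
1.8606e-01	9.8810e+01
1.9516e-01	8.4615e+01
2.0470e-01	7.2274e+01
2.1470e-01	6.1766e+01
2.2520e-01	5.3001e+01
2.3621e-01	4.5827e+01
2.4776e-01	4.0053e+01
2.5987e-01	3.5467e+01
2.7257e-01	3.1859e+01
2.8590e-01	2.9028e+01
2.9987e-01	2.6796e+01
3.1453e-01	2.5002e+01
3.2991e-01	2.3511e+01
3.4604e-01	2.2200e+01
3.6295e-01	2.0970e+01
3.8070e-01	1.9738e+01
3.9931e-01	1.8444e+01
4.1883e-01	1.7056e+01
4.3930e-01	1.5568e+01
4.6078e-01	1.4000e+01
4.8330e-01	1.2390e+01
5.0693e-01	1.0789e+01
5.3171e-01	9.2481e+00
5.5771e-01	7.8126e+00
5.8497e-01	6.5158e+00
6.1357e-01	5.3762e+00
6.4356e-01	4.3983e+00
6.7502e-01	3.5754e+00
7.0802e-01	2.8929e+00
7.4263e-01	2.3323e+00
7.7894e-01	1.8746e+00
8.1702e-01	1.5024e+00
8.5696e-01	1.2012e+00
8.9885e-01	9.5934e-01
9.4279e-01	7.6794e-01
9.8888e-01	6.1947e-01
1.0372e+00	5.0708e-01
1.0879e+00	4.2398e-01
1.1411e+00	3.6341e-01
1.1969e+00	3.1894e-01
1.2554e+00	2.8499e-01
1.3168e+00	2.5718e-01
1.3812e+00	2.3254e-01
1.4487e+00	2.0935e-01
1.5195e+00	1.8685e-01
1.5938e+00	1.6495e-01
1.6717e+00	1.4387e-01
1.7534e+00	1.2395e-01
1.8391e+00	1.0550e-01
1.9290e+00	8.8718e-02
2.0233e+00	7.3733e-02
2.1223e+00	6.0552e-02
2.2260e+00	4.9117e-02
2.3348e+00	3.9322e-02
2.4490e+00	3.1035e-02
2.5687e+00	2.4116e-02
2.6943e+00	1.8423e-02
2.8260e+00	1.3820e-02
2.9641e+00	1.0169e-02
3.1090e+00	7.3374e-03
3.2610e+00	5.1934e-03
3.4204e+00	3.6105e-03
3.5876e+00	2.4705e-03
3.7630e+00	1.6685e-03
3.9470e+00	1.1153e-03
4.1399e+00	7.3972e-04
4.3423e+00	4.8727e-04
4.5546e+00	3.1848e-04
4.7773e+00	2.0583e-04
5.0108e+00	1.3077e-04
5.2558e+00	8.1055e-05
5.5127e+00	4.8581e-05
5.7822e+00	2.7897e-05
6.0649e+00	1.5211e-05
6.3614e+00	7.8097e-06
6.6723e+00	3.7477e-06
6.9985e+00	1.6707e-06
7.3407e+00	6.8919e-07
7.6995e+00	2.6306e-07
8.0759e+00	9.3626e-08
8.4707e+00	3.1769e-08
8.8848e+00	1.0756e-08
9.3192e+00	3.8863e-09
9.7747e+00	1.5840e-09
1.0253e+01	7.2672e-10
1.0754e+01	3.5637e-10
1.1280e+01	1.7675e-10
1.1831e+01	8.5455e-11
1.2409e+01	3.9485e-11
1.3016e+01	1.7274e-11
1.3652e+01	7.1293e-12
1.4320e+01	2.7713e-12
1.5020e+01	1.0123e-12
1.5754e+01	3.4564e-13
1.6524e+01	1.0929e-13
1.7332e+01	3.1588e-14
1.8179e+01	8.2155e-15
1.9068e+01	1.8907e-15
2.0000e+01	3.7840e-16
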