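# element	H
# Z	1
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-0.500000
r_bohr	rho_e_bohr3
1.5000e-03	3.1569e-01
1.5733e-03	3.1568e-01
1.6502e-03	3.1567e-01
1.7309e-03	3.1566e-01
1.8155e-03	3.1564e-01
1.9043e-03	3.1563e-01
1.9974e-03	3.1562e-01
2.0950e-03	3.1560e-01
2.1974e-03	3.1558e-01
2.3049e-03	3.1556e-01
2.4175e-03	3.1554e-01
2.5357e-03	3.1551e-01
2.6597e-03	3.1549e-01
2.7897e-03	3.1546e-01
2.9261e-03	3.1542e-01
3.0691e-03	3.1539e-01
3.2192e-03	3.1535e-01
3.3765e-03	3.1531e-01
3.5416e-03	3.1526e-01
3.7148e-03	3.1521e-01
3.8964e-03	3.1515e-01
4.0868e-03	3.1509e-01
4.2866e-03	3.1502e-01
4.4962e-03	3.1495e-01
4.7160e-03	3.1487e-01
4.9465e-03	3.1478e-01
5.1883e-03	3.1468e-01
5.4420e-03	3.1458e-01
5.7080e-03	3.1446e-01
5.9871e-03	3.1434e-01
6.2797e-03	3.1421e-01
6.5867e-03	3.1406e-01
6.9087e-03	3.1390e-01
7.2465e-03	3.1373e-01
7.6007e-03	3.1354e-01
7.9723e-03	3.1334e-01
8.3620e-03	3.1312e-01
8.7708e-03	3.1289e-01
9.1996e-03	3.1264e-01
9.6493e-03	3.1237e-01
1.0121e-02	3.1208e-01
1.0616e-02	3.1178e-01
1.1135e-02	3.1145e-01
1.1679e-02	3.1111e-01
1.2250e-02	3.1074e-01
1.2849e-02	3.1035e-01
1.3477e-02	3.0994e-01
1.4136e-02	3.0951e-01
1.4827e-02	3.0906e-01
1.5552e-02	3.0859e-01
1.6312e-02	3.0810e-01
1.7109e-02	3.0759e-01
1.7946e-02	3.0706e-01
1.8823e-02	3.0650e-01
1.9743e-02	3.0593e-01
2.0709e-02	3.0534e-01
2.1721e-02	3.0472e-01
2.2783e-02	3.0408e-01
2.3897e-02	3.0341e-01
2.5065e-02	3.0272e-01
2.6290e-02	3.0199e-01
2.7575e-02	3.0123e-01
2.8923e-02	3.0043e-01
3.0337e-02	2.9959e-01
3.1820e-02	2.9871e-01
3.3376e-02	2.9778e-01
3.5008e-02	2.9681e-01
3.6719e-02	2.9579e-01
3.8514e-02	2.9472e-01
4.0397e-02	2.9361e-01
4.2372e-02	2.9244e-01
4.4443e-02	2.9123e-01
4.6616e-02	2.8996e-01
4.8894e-02	2.8864e-01
5.1285e-02	2.8726e-01
5.3792e-02	2.8583e-01
5.6422e-02	2.8434e-01
5.9180e-02	2.8278e-01
6.2073e-02	2.8115e-01
6.5107e-02	2.7945e-01
6.8290e-02	2.7768e-01
7.1629e-02	2.7583e-01
7.5130e-02	2.7391e-01
7.8803e-02	2.7190e-01
8.2655e-02	2.6981e-01
8.6696e-02	2.6764e-01
9.0934e-02	2.6537e-01
9.5380e-02	2.6302e-01
1.0004e-01	2.6058e-01
1.0493e-01	2.5805e-01
1.1006e-01	2.5541e-01
1.1544e-01	2.5268e-01
1.2109e-01	2.4985e-01
1.2701e-01	2.4691e-01
1.3322e-01	2.4386e-01
1.3973e-01	2.4071e-01
1.4656e-01	2.3744e-01
1.5372e-01	2.3406e-01
1.6124e-01	2.3057e-01
1.6912e-01	2.2696e-01
1.7739e-01	2.2324e-01
1.8606e-01	2.1940e-01
1.9516e-01	2.1545e-01
2.0470e-01	2.1137e-01
2.1470e-01	2.0719e-01
2.2520e-01	2.0288e-01
2.3621e-01	1.9846e-01
2.4776e-01	1.9393e-01
2.5987e-01	1.8929e-01
2.7257e-01	1.8454e-01
2.8590e-01	1.7969e-01
2.9987e-01	1.7474e-01
3.1453e-01	1.6969e-01
3.2991e-01	1.6455e-01
3.4604e-01	1.5933e-01
3.6295e-01	1.5403e-01
3.8070e-01	1.4866e-01
3.9931e-01	1.4322e-01
4.1883e-01	1.3774e-01
4.3930e-01	1.3221e-01
4.6078e-01	1.2666e-01
4.8330e-01	1.2108e-01
5.0693e-01	1.1549e-01
5.3171e-01	1.0990e-01
5.5771e-01	1.0434e-01
5.8497e-01	9.8799e-02
6.1357e-01	9.3307e-02
6.4356e-01	8.7874e-02
6.7502e-01	8.2515e-02
7.0802e-01	7.7245e-02
7.4263e-01	7.2079e-02
7.7894e-01	6.7030e-02
8.1702e-01	6.2115e-02
8.5696e-01	5.7346e-02
8.9885e-01	5.2737e-02
9.4279e-01	4.8300e-02
9.8888e-01	4.4047e-02
1.0372e+00	3.9988e-02
1.0879e+00	3.6131e-02
1.1411e+00	3.2485e-02
1.1969e+00	2.9056e-02
1.2554e+00	2.5847e-02
1.3168e+00	2.2862e-02
1.3812e+00	2.0100e-02
1.4487e+00	1.7561e-02
1.5195e+00	1.5242e-02
1.5938e+00	1.3137e-02
1.6717e+00	1.1242e-02
1.7534e+00	9.5467e-03
1.8391e+00	8.0427e-03
1.9290e+00	6.7190e-03
2.0233e+00	5.5641e-03
2.1223e+00	4.5654e-03
2.2260e+00	3.7099e-03
2.3348e+00	2.9843e-03
2.4490e+00	2.3752e-03
2.5687e+00	1.8695e-03
2.6943e+00	1.4543e-03
2.8260e+00	1.1175e-03
2.9641e+00	8.4771e-04
3.1090e+00	6.3443e-04
3.2610e+00	4.6814e-04
3.4204e+00	3.4033e-04
3.5876e+00	2.4359e-04
3.7630e+00	1.7152e-04
3.9470e+00	1.1872e-04
4.1399e+00	8.0709e-05
4.3423e+00	5.3844e-05
4.5546e+00	3.5218e-05
4.7773e+00	2.2561e-05
5.0108e+00	1.4142e-05
5.2558e+00	8.6641e-06
5.5127e+00	5.1828e-06
5.7822e+00	3.0237e-06
6.0649e+00	1.7184e-06
6.3614e+00	9.5001e-07
6.6723e+00	5.1012e-07
6.9985e+00	2.6559e-07
7.3407e+00	1.3384e-07
7.6995e+00	6.5176e-08
8.0759e+00	3.0635e-08
8.4707e+00	1.3889e-08
8.8848e+00	6.0722e-09
9.3192e+00	2.5593e-09
9.7747e+00	1.0389e-09
1.0253e+01	4.0512e-10
1.0754e+01	1.5099e-10
1.1280e+01	5.3386e-11
1.1831e+01	1.7742e-11
1.2409e+01	5.4875e-12
1.3016e+01	1.5658e-12
1.3652e+01	4.0994e-13
1.4320e+01	9.8465e-14
1.5020e+01	2.1865e-14
1.5754e+01	4.5618e-15
1.6524e+01	9.1456e-16
1.7332e+01	1.7984e-16
1.8179e+01	3.4920e-17
1.9068e+01	6.5953e-18
2.0000e+01	1.1717e-18
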