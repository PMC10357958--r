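# label: PEDOT_PSS preset (|Z| = 30000 ohm at 1 kHz)
freq_hz,z_real_ohm,z_imag_ohm
1,1647968.49516,-20901306.4841
1.77827941004,955045.237032,-12096881.6998
3.16227766017,554007.594383,-7001215.30542
5.6234132519,321902.250921,-4052037.29102
10,187568.500832,-2345165.15942
17.7827941004,109821.232528,-1357292.45067
31.6227766017,64824.0689358,-785549.277522
56.234132519,38781.4210651,-454646.061805
100,23708.9264016,-263131.858725
177.827941004,14985.5394208,-152290.717754
316.227766017,9936.7746266,-88140.0786143
562.34132519,7014.74147562,-51012.1271521
1000,5323.57975914,-29523.8801405
1778.27941004,4344.79964149,-17087.2995739
3162.27766017,3778.31891444,-9889.47947689
5623.4132519,3450.46140249,-5723.65480578
10000,3260.70993698,-3312.63383602
17782.7941004,3150.88900151,-1917.22654561
31622.7766017,3087.32881853,-1109.61784765
56234.132519,3050.54260065,-642.204631814
100000,3029.25213605,-371.683629636
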