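marker	aligned_length	variable_sites	mean_distance
atpF-atpH	493	85	0.0960
rbcL	1461	92	0.0366
atpF	949	147	0.1089
rpoC1	740	94	0.0716
rps12	540	5	0.0053
rpl2	664	8	0.0071
ndhA	1091	235	0.1413
ycf3_1	778	72	0.0551
ycf3_2	827	72	0.0503
clpP_1	868	122	0.0875
clpP_2	688	94	0.0861
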