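site	temperature	treatment	rate
WV	65	13C+15N	1.43
WV	65	13C+14N	1.68
WV	65	13C	1.38
WV	45	13C+15N	1.82
WV	45	13C+14N	2.49
WV	45	13C	1.87
WV	30	13C+15N	1.67
WV	30	13C+14N	2.04
WV	30	13C	1.63
YV	65	13C+15N	BDL
YV	65	13C+14N	BDL
YV	65	13C	BDL
YV	45	13C+15N	0.017
YV	45	13C+14N	0.012
YV	45	13C	0.013
YV	30	13C+15N	0.054
YV	30	13C+14N	0.090
YV	30	13C	0.046
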