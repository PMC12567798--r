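method	TP	TN	FP	FN	coverage
ProToxin	225	457	17	54	1.000
XGBoost-88	229	453	21	50	1.000
ToxinPred2	194	451	23	85	1.000
ToxinPred2-hybrid	225	430	44	54	1.000
ToxIBTL	161	459	15	118	1.000
VISH-Pred	210	451	7	67	0.976
CSM-Toxin	203	469	5	76	1.000
MultiToxPred	172	278	196	107	1.000
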