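lab	parent	num.vars	pAsc.frac	pPer1.frac	iAsc.frac
1	-1	120	50.0%	40.0%	20.0%
2	1	40	50.0%	60.0%	30.0%
3	1	65	0	0	50.0%
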