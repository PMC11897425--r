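sample	parent	rank	rankTitle
pAsc		1	Diagnosis
pPer1		1	Diagnosis
iAsc	pAsc	2	Interval
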