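sample	timePoint	location
pAsc	T1	Asc
pPer1	T1	Per
iAsc	T2	Asc
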