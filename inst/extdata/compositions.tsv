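sample	subclone	clonalPrevalence
pAsc	1	0.5
pAsc	2	0.5
pPer1	1	0.4
pPer1	2	0.6
iAsc	1	0.2
iAsc	2	0.3
iAsc	3	0.5
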