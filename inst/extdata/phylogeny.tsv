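subclone	parent	branchLength
1		120
2	1	40
3	1	65
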