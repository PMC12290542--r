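code	name
1	SB
2	CA1
3	CA2
4	CA3
5	CA4
6	DG
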