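x	y	z
-0.414644	0.08967	0.905555
0.397986	-0.146892	0.905555
0.930119	0.167018	0.327084
-0.69515	0.640143	0.327084
-0.649616	-0.717501	0.25138
0.163014	-0.954062	0.25138
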