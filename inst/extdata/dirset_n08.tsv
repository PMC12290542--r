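x	y	z
-0.142428	-0.543653	0.827137
-0.54811	0.124176	0.827137
0.164831	0.629451	0.759356
0.634577	-0.143839	0.759356
0.203547	-0.95882	0.198071
-0.757088	0.622564	0.198071
0.584238	0.811509	0.010903
0.989452	0.144451	0.010903
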