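x	y	z
-0.056447	-0.194026	0.979371
0.141231	0.187841	0.971993
-0.230238	0.34277	0.910769
-0.419063	-0.074059	0.904932
0.460945	-0.068089	0.884813
0.232644	-0.441034	0.866814
0.381706	0.487751	0.785111
-0.118617	-0.644422	0.755414
-0.476672	-0.465256	0.745869
-0.622415	0.248008	0.742355
0.040547	0.67343	0.738138
0.682663	0.249747	0.686729
0.586951	-0.468152	0.660548
-0.351119	0.681852	0.641712
-0.771943	-0.155542	0.616368
0.819276	-0.113561	0.562041
0.296567	-0.774439	0.558831
-0.692422	0.546644	0.470885
0.326962	0.839655	0.433676
0.668303	0.60621	0.431138
-0.444092	-0.796226	0.41086
-0.062336	-0.913178	0.402766
-0.751247	-0.53245	0.390033
-0.910787	0.186394	0.368408
-0.093482	0.926921	0.363427
0.831366	-0.454917	0.31919
0.925866	0.224336	0.304048
0.577194	-0.781799	0.235877
-0.497641	0.840747	0.213302
-0.961037	-0.19869	0.192171
0.225021	-0.970187	0.090019
-0.832334	0.548028	0.082982
0.987449	-0.137002	0.078583
0.841869	0.53841	0.037036
0.188547	0.981831	0.021395
0.560228	0.828198	0.015219
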