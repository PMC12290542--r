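x	y	z
-0.159541	0.09467	0.982642
0.00403	-0.202671	0.979239
0.192482	0.084028	0.977696
0.045336	0.390119	0.919648
-0.349028	-0.203825	0.914677
0.34962	-0.204487	0.914304
-0.285906	0.387175	0.876557
-0.494751	0.074182	0.865863
0.376219	0.33512	0.863802
-0.168317	-0.475855	0.863268
0.159714	-0.497444	0.852667
0.551052	0.039341	0.833543
0.466725	-0.470519	0.748852
-0.121671	0.657519	0.743549
0.199473	0.646597	0.73629
-0.581517	0.351807	0.733532
-0.508068	-0.452668	0.732775
-0.678379	-0.172568	0.714159
0.68041	-0.242199	0.691651
0.680942	0.297414	0.669226
0.026147	-0.744038	0.667626
0.496888	0.567883	0.65621
-0.296458	-0.695181	0.654856
-0.444309	0.631433	0.635517
-0.785646	0.124335	0.606054
0.349808	-0.730053	0.587075
0.827841	0.011687	0.560841
-0.742847	-0.44998	0.495677
0.096	0.863672	0.494829
0.660393	-0.565997	0.493486
-0.235542	0.843019	0.483569
-0.749614	0.462248	0.473715
-0.535558	-0.71829	0.444113
0.410654	0.802106	0.433577
-0.893402	-0.130858	0.429778
-0.203338	-0.891073	0.405762
0.696554	0.59502	0.400955
0.862893	-0.309493	0.399537
0.867424	0.305849	0.39247
0.139007	-0.909647	0.391433
-0.594327	0.724275	0.349573
-0.922267	0.234867	0.307019
0.504687	-0.808174	0.303556
0.967729	-0.029659	0.250242
-0.89785	-0.385015	0.21361
-0.047956	0.978006	0.202987
-0.374553	0.906673	0.194046
0.795311	-0.575321	0.191014
-0.712802	-0.676859	0.183779
0.279289	0.946474	0.161817
-0.425499	-0.891774	0.153917
-0.826626	0.542646	0.14908
0.587339	0.798903	0.129563
-0.992329	-0.014254	0.122801
-0.076494	-0.990622	0.113209
0.272641	-0.956596	0.102914
0.826235	0.554113	0.101468
0.963031	0.255868	0.084274
0.954018	-0.296147	0.046336
-0.61931	0.785146	0.001208
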