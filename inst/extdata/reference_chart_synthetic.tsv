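week	sex	parity	bw_mean	bw_sd	pw_mean	pw_sd
34	female	nulliparous	2150	330	398	85
35	female	nulliparous	2380	340	440	87
36	female	nulliparous	2580	350	477	89
37	female	nulliparous	2760	360	511	91
38	female	nulliparous	2930	370	542	93
39	female	nulliparous	3050	380	564	95
40	female	nulliparous	3150	390	583	97
41	female	nulliparous	3230	400	598	99
42	female	nulliparous	3280	410	607	101
34	male	nulliparous	2210	330	408	85
35	male	nulliparous	2440	340	450	87
36	male	nulliparous	2640	350	487	89
37	male	nulliparous	2820	360	521	91
38	male	nulliparous	2990	370	552	93
39	male	nulliparous	3110	380	574	95
40	male	nulliparous	3210	390	593	97
41	male	nulliparous	3290	400	608	99
42	male	nulliparous	3340	410	617	101
34	female	parous	2190	330	406	85
35	female	parous	2420	340	448	87
36	female	parous	2620	350	485	89
37	female	parous	2800	360	519	91
38	female	parous	2970	370	550	93
39	female	parous	3090	380	572	95
40	female	parous	3190	390	591	97
41	female	parous	3270	400	606	99
42	female	parous	3320	410	615	101
34	male	parous	2250	330	416	85
35	male	parous	2480	340	458	87
36	male	parous	2680	350	495	89
37	male	parous	2860	360	529	91
38	male	parous	3030	370	560	93
39	male	parous	3150	380	582	95
40	male	parous	3250	390	601	97
41	male	parous	3330	400	616	99
42	male	parous	3380	410	625	101
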