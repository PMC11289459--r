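snp_id	bp	chr	ld_block	effect_allele	meta_p	meta_or	swe_p	swe_or	ita_p	ita_or
rs900347	145726727	1	1	A	0.0285	0.90	0.0352	0.87	0.3624	0.94
rs11800992	146501783	1	2	A	0.0093	0.82	0.0260	0.78	0.1399	0.85
rs72691008	146708291	1	3	A	0.0017	0.69	0.0083	0.69	0.0895	0.70
rs7514808	146570076	1	4	A	0.0286	0.89	0.0367	0.86	0.3632	0.93
rs72706463	146615555	1	5	A	0.0458	1.29	0.1141	1.37	0.2002	1.24
rs10453880	146693689	1	6	T	0.0065	1.26	0.1083	1.21	0.0236	1.32
rs145465008	146630173	1	7	C	0.0293	1.51	0.4867	1.17	0.0048	2.54
rs115153075	146978424	1	8	T	0.0006	1.48	0.0058	1.42	0.0303	1.74
rs12096043	147060953	1	9	T	0.0001	1.84	0.0005	2.03	0.0633	1.58
rs672619	147058575	1	10	T	0.0013	1.34	0.0374	1.32	0.0146	1.35
rs10494248	147108260	1	11	A	0.0079	1.72	0.0270	1.68	0.1386	1.82
rs140566115	147126437	1	12	A	0.0244	1.53	0.0335	1.66	0.3586	1.34
rs116430961	147312516	1	13	C	0.0101	1.62	0.1335	1.44	0.0265	1.93
rs61740912	147313970	1	14	G	0.0012	1.86	0.0098	1.81	0.0483	1.97
rs112044341	147317235	1	15	A	0.0193	1.47	0.0577	1.46	0.1707	1.49
rs74123747	147382534	1	16	T	0.0496	1.27	0.2194	1.20	0.0813	1.50
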