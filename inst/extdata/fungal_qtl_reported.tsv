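id	taxon	rank	chrom	snp	lod	start_bp	end_bp	diff_mb	h2_lod_pct	rho_sex	rho_gen	rho_diet	model
2	Basidiomycota	Phylum	7	UNC12630138	10.35	36217417	36377617	0.1602	10.8	0.0672	-0.0234	0.0718	IntDiet
2	Basidiomycota	Phylum	11	UNC20492040	9.07	117545132	118530429	0.985297	9.53	0.0672	-0.0234	0.0718	IntDiet
1616	Zygomycota;Incertae_sedis_10	Class	7	UNC13835983	11.19	129034744	130149978	1.115234	11.63	0.1847	-0.0781	0.034	IntDiet
112	Polyporales	Order	6	UNC12042546	10.37	126848048	127850668	1.00262	10.82	0.0446	-0.0563	0.0313	IntDiet
40	Russulales	Order	9	UNC16882054	11.7	93022854	94468212	1.445358	12.12	0.0365	-0.0689	0.0062	IntDiet
121	Cantharellales	Order	18	JAX00081898	9.39	31199252	32034289	0.835037	9.85	0.123	-0.0493	-0.0058	IntDiet
2156	Hypocreales_unidentified	Family	13	UNC22815472	9.97	70348004	71076189	0.728185	10.43	0.1903	-0.0743	0.0194	IntDiet
2314	Corticiaceae	Family	18	UNC28777523	13.46	14637698	15762396	1.124698	13.81	0.1452	-0.0942	-0.1013	IntDiet
2157	Hypocreales_unidentified_1	Genus	13	UNC22815472	8.86	70693059	70712481	0.019422	9.32	0.1893	-0.0736	0.0203	IntDiet
5603	Vuilleminia	Genus	18	UNC28777036	9.63	14637698	16134939	1.497241	10.09	0.1743	-0.1016	-0.0759	IntDiet
1758	Geosmithia	Genus	X	UNC31499614	10.76	153533292	158259643	4.726351	11.2	0.2821	-0.2599	0.0715	IntDiet
OTU2352	Penicillium citreonigrum	Species	1	CEAJAX00009745	11.7	133222151	133859717	0.637566	11.86	0.0075	-0.1375	-0.0268	IntDiet
OTU29	Malassezia restricta	Species	8	UNC08061940	8.77	22671231	23905921	1.23469	9.03	-0.0619	-0.0125	NA	IntDiet
OTU2243	Penicillium spathulatum	Species	18	UNC29116030	9.4	41708067	41733945	0.025878	9.25	-0.0099	-0.3142	0.0578	IntDiet
OTU2213	Penicillium spathulatum	Species	18	UNC29082687	9.14	39047223	39715173	0.66795	9.38	-0.0385	-0.3344	0.0514	IntDiet
OTU298	Aspergillus nidulans	Species	19	UNC30601828	8.87	60383903	61103683	0.71978	9.13	0.0137	0.1997	-0.2017	IntDiet
OTU941	Aspergillus glabripes	Species	X	UNC20010517	9.77	82219367	82464595	0.245228	10	-0.033	0.2072	-0.0592	IntDiet
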