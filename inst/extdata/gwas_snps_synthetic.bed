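chr1	2063296	2063297	rs000001
chr2	2291605	2291606	rs000002
chr3	2000278	2000279	rs000003
chr4	2142071	2142072	rs000004
chr5	2398978	2398979	rs000005
chr6	2091749	2091750	rs000006
chr7	2281781	2281782	rs000007
chr8	2410928	2410929	rs000008
chr9	2133110	2133111	rs000009
chr10	2335691	2335693	rs000010
chr11	2298266	2298267	rs000011
chr12	2063311	2063312	rs000012
chr13	2178267	2178268	rs000013
chr14	2236354	2236355	rs000014
chr15	2403686	2403688	rs000015
chr16	2088701	2088702	rs000016
chr17	2075794	2075795	rs000017
chr18	2113715	2113716	rs000018
chr19	2092878	2092879	rs000019
chr20	2437075	2437076	rs000020
chr21	2184656	2184657	rs000021
chr22	2203604	2203605	rs000022
chr1	3815852	3815853	rs000023
chr2	4803453	4803454	rs000024
chr3	6171598	6171599	rs000025
chr4	5793246	5793247	rs000026
chr5	5304332	5304333	rs000027
chr6	5403423	5403424	rs000028
chr7	6019633	6019634	rs000029
chr8	6558207	6558208	rs000030
chr9	5320979	5320980	rs000031
chr10	6031250	6031251	rs000032
chr11	4259981	4259982	rs000033
chr12	5095978	5095979	rs000034
chr13	5725336	5725337	rs000035
chr14	3832076	3832077	rs000036
chr15	5493594	5493595	rs000037
chr16	4346324	4346325	rs000038
chr17	4390923	4390924	rs000039
chr18	6035880	6035881	rs000040
chr19	6016580	6016581	rs000041
chr19	6511516	6511517	rs000042
chr20	4998450	4998451	rs000043
chr20	5220422	5220424	rs000044
chr21	4395239	4395240	rs000045
chr21	5084449	5084450	rs000046
chr22	5117129	5117130	rs000047
chr22	5836538	5836539	rs000048
chr1	7652344	7652345	rs000049
chr1	8352359	8352360	rs000050
chr2	8551698	8551699	rs000051
chr2	9338161	9338162	rs000052
chr3	8333700	8333701	rs000053
chr3	9269584	9269586	rs000054
chr4	8147895	8147896	rs000055
chr4	8851548	8851549	rs000056
chr5	8611030	8611031	rs000057
chr5	9163825	9163826	rs000058
chr6	9514677	9514678	rs000059
chr6	10029338	10029339	rs000060
chr7	10003171	10003172	rs000061
chr7	10521768	10521769	rs000062
chr7	10739989	10739990	rs000063
chr7	11556273	11556274	rs000064
chr8	9142530	9142531	rs000065
chr8	9479749	9479750	rs000066
chr8	10131303	10131304	rs000067
chr8	10306052	10306054	rs000068
chr9	7111662	7111663	rs000069
chr9	8046265	8046267	rs000070
chr9	8710282	8710283	rs000071
chr9	9315932	9315933	rs000072
chr10	9243410	9243411	rs000073
chr10	10182254	10182255	rs000074
chr10	10991559	10991560	rs000075
chr10	11610361	11610362	rs000076
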