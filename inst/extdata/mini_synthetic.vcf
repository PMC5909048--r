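##fileformat=VCFv4.2
##source=abploidy
##contig=<ID=chr1,length=60000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
chr1	224	.	A	T	.	PASS	.	GT:AD	0/1:58,52	0/1:57,57
chr1	576	.	A	T	.	PASS	.	GT:AD	0/1:47,49	0/1:119,99
chr1	875	.	A	T	.	PASS	.	GT:AD	0/1:24,32	0/1:59,76
chr1	935	.	A	T	.	PASS	.	GT:AD	0/1:48,52	0/1:22,32
chr1	1024	.	A	T	.	PASS	.	GT:AD	0/1:72,71	0/1:51,41
chr1	1155	.	A	T	.	PASS	.	GT:AD	0/1:48,66	0/1:59,44
chr1	1385	.	A	T	.	PASS	.	GT:AD	0/1:38,33	0/1:40,46
chr1	1761	.	A	T	.	PASS	.	GT:AD	0/1:31,23	0/1:46,42
chr1	1989	.	A	T	.	PASS	.	GT:AD	0/1:69,53	0/1:47,53
chr1	2353	.	A	T	.	PASS	.	GT:AD	0/1:50,43	0/1:52,42
chr1	2435	.	A	T	.	PASS	.	GT:AD	0/1:45,44	0/1:45,44
chr1	2589	.	A	T	.	PASS	.	GT:AD	0/1:50,56	0/1:38,40
chr1	2601	.	A	T	.	PASS	.	GT:AD	0/1:63,65	0/1:45,35
chr1	2856	.	A	T	.	PASS	.	GT:AD	0/1:39,52	0/1:64,42
chr1	4069	.	A	T	.	PASS	.	GT:AD	0/1:48,62	0/1:67,62
chr1	4164	.	A	T	.	PASS	.	GT:AD	0/1:26,19	0/1:49,56
chr1	4214	.	A	T	.	PASS	.	GT:AD	0/1:85,94	0/1:28,25
chr1	5305	.	A	T	.	PASS	.	GT:AD	0/1:45,37	0/1:75,64
chr1	5772	.	A	T	.	PASS	.	GT:AD	0/1:33,45	0/1:47,52
chr1	6055	.	A	T	.	PASS	.	GT:AD	0/1:31,34	0/1:89,87
chr1	7340	.	A	T	.	PASS	.	GT:AD	0/1:54,61	0/1:71,72
chr1	7802	.	A	T	.	PASS	.	GT:AD	0/1:60,54	0/1:43,33
chr1	7847	.	A	T	.	PASS	.	GT:AD	0/1:43,38	0/1:35,33
chr1	7963	.	A	T	.	PASS	.	GT:AD	0/1:53,58	0/1:47,53
chr1	8243	.	A	T	.	PASS	.	GT:AD	0/1:45,44	0/1:50,49
chr1	9281	.	A	T	.	PASS	.	GT:AD	0/1:76,99	0/1:48,44
chr1	9331	.	A	T	.	PASS	.	GT:AD	0/1:40,48	0/1:52,70
chr1	9369	.	A	T	.	PASS	.	GT:AD	0/1:15,50	0/1:21,17
chr1	9508	.	A	T	.	PASS	.	GT:AD	0/1:49,51	0/1:63,44
chr1	10965	.	A	T	.	PASS	.	GT:AD	0/1:41,37	0/1:45,54
chr1	11010	.	A	T	.	PASS	.	GT:AD	0/1:59,75	0/1:20,37
chr1	11024	.	A	T	.	PASS	.	GT:AD	0/1:65,55	0/1:25,29
chr1	11784	.	A	T	.	PASS	.	GT:AD	0/1:38,43	0/1:68,47
chr1	11889	.	A	T	.	PASS	.	GT:AD	0/1:53,62	0/1:74,75
chr1	12011	.	A	T	.	PASS	.	GT:AD	0/1:44,48	0/1:32,34
chr1	12578	.	A	T	.	PASS	.	GT:AD	0/1:60,42	0/1:16,95
chr1	13005	.	A	T	.	PASS	.	GT:AD	0/1:46,45	0/1:60,64
chr1	14444	.	A	T	.	PASS	.	GT:AD	0/1:65,70	0/1:46,61
chr1	16080	.	A	T	.	PASS	.	GT:AD	0/1:28,27	0/1:69,64
chr1	17086	.	A	T	.	PASS	.	GT:AD	0/1:65,69	0/1:41,19
chr1	17090	.	A	T	.	PASS	.	GT:AD	0/1:36,21	0/1:62,66
chr1	18233	.	A	T	.	PASS	.	GT:AD	0/1:42,43	0/1:35,46
chr1	18300	.	A	T	.	PASS	.	GT:AD	0/1:67,67	0/1:46,45
chr1	18748	.	A	T	.	PASS	.	GT:AD	0/1:25,32	0/1:26,31
chr1	18825	.	A	T	.	PASS	.	GT:AD	0/1:46,33	0/1:45,53
chr1	19025	.	A	T	.	PASS	.	GT:AD	0/1:48,49	0/1:46,46
chr1	19157	.	A	T	.	PASS	.	GT:AD	0/1:58,46	0/1:58,37
chr1	19362	.	A	T	.	PASS	.	GT:AD	0/1:33,31	0/1:47,35
chr1	19507	.	A	T	.	PASS	.	GT:AD	0/1:27,54	0/1:26,40
chr1	19872	.	A	T	.	PASS	.	GT:AD	0/1:48,61	0/1:34,27
chr1	20179	.	A	T	.	PASS	.	GT:AD	0/1:32,40	0/1:56,60
chr1	21029	.	A	T	.	PASS	.	GT:AD	0/1:38,39	0/1:45,35
chr1	22955	.	A	T	.	PASS	.	GT:AD	0/1:63,58	0/1:39,34
chr1	24842	.	A	T	.	PASS	.	GT:AD	0/1:55,41	0/1:42,52
chr1	25436	.	A	T	.	PASS	.	GT:AD	0/1:26,25	0/1:56,48
chr1	25687	.	A	T	.	PASS	.	GT:AD	0/1:57,61	0/1:45,35
chr1	26648	.	A	T	.	PASS	.	GT:AD	0/1:66,73	0/1:80,71
chr1	26727	.	A	T	.	PASS	.	GT:AD	0/1:25,27	0/1:61,51
chr1	27132	.	A	T	.	PASS	.	GT:AD	0/1:35,50	0/1:27,39
chr1	27958	.	A	T	.	PASS	.	GT:AD	0/1:40,49	0/1:52,47
chr1	28654	.	A	T	.	PASS	.	GT:AD	0/1:67,55	0/1:90,40
chr1	29018	.	A	T	.	PASS	.	GT:AD	0/1:26,37	0/1:12,19
chr1	29099	.	A	T	.	PASS	.	GT:AD	0/1:50,51	0/1:39,43
chr1	29307	.	A	T	.	PASS	.	GT:AD	0/1:50,62	0/1:44,55
chr1	29372	.	A	T	.	PASS	.	GT:AD	0/1:63,80	0/1:57,42
chr1	29557	.	A	T	.	PASS	.	GT:AD	0/1:63,67	0/1:56,46
chr1	30237	.	A	T	.	PASS	.	GT:AD	0/1:58,61	0/1:29,46
chr1	30411	.	A	T	.	PASS	.	GT:AD	0/1:23,35	0/1:41,64
chr1	31432	.	A	T	.	PASS	.	GT:AD	0/1:48,48	0/1:26,57
chr1	31496	.	A	T	.	PASS	.	GT:AD	0/1:61,68	0/1:31,72
chr1	31649	.	A	T	.	PASS	.	GT:AD	0/1:43,40	0/1:57,102
chr1	32080	.	A	T	.	PASS	.	GT:AD	0/1:40,51	0/1:24,54
chr1	32549	.	A	T	.	PASS	.	GT:AD	0/1:48,120	0/1:29,50
chr1	33213	.	A	T	.	PASS	.	GT:AD	0/1:73,83	0/1:26,63
chr1	33332	.	A	T	.	PASS	.	GT:AD	0/1:39,27	0/1:30,52
chr1	33803	.	A	T	.	PASS	.	GT:AD	0/1:29,24	0/1:35,70
chr1	34760	.	A	T	.	PASS	.	GT:AD	0/1:35,40	0/1:32,65
chr1	36504	.	A	T	.	PASS	.	GT:AD	0/1:49,52	0/1:38,70
chr1	37392	.	A	T	.	PASS	.	GT:AD	0/1:63,52	0/1:38,62
chr1	37968	.	A	T	.	PASS	.	GT:AD	0/1:32,53	0/1:37,106
chr1	39358	.	A	T	.	PASS	.	GT:AD	0/1:36,41	0/1:35,56
chr1	40610	.	A	T	.	PASS	.	GT:AD	0/1:41,30	0/1:15,35
chr1	40762	.	A	T	.	PASS	.	GT:AD	0/1:41,54	0/1:35,70
chr1	41749	.	A	T	.	PASS	.	GT:AD	0/1:54,51	0/1:25,40
chr1	41905	.	A	T	.	PASS	.	GT:AD	0/1:26,22	0/1:26,43
chr1	42426	.	A	T	.	PASS	.	GT:AD	0/1:63,61	0/1:27,55
chr1	42631	.	A	T	.	PASS	.	GT:AD	0/1:17,18	0/1:46,68
chr1	43950	.	A	T	.	PASS	.	GT:AD	0/1:75,86	0/1:50,90
chr1	44536	.	A	T	.	PASS	.	GT:AD	0/1:42,28	0/1:18,32
chr1	44628	.	A	T	.	PASS	.	GT:AD	0/1:34,46	0/1:22,43
chr1	45756	.	A	T	.	PASS	.	GT:AD	0/1:42,31	0/1:40,105
chr1	45969	.	A	T	.	PASS	.	GT:AD	0/1:44,35	0/1:30,67
chr1	46434	.	A	T	.	PASS	.	GT:AD	0/1:102,88	0/1:31,48
chr1	46754	.	A	T	.	PASS	.	GT:AD	0/1:59,48	0/1:31,60
chr1	46915	.	A	T	.	PASS	.	GT:AD	0/1:27,17	0/1:31,73
chr1	47110	.	A	T	.	PASS	.	GT:AD	0/1:49,48	0/1:38,77
chr1	48569	.	A	T	.	PASS	.	GT:AD	0/1:94,73	0/1:43,86
chr1	48714	.	A	T	.	PASS	.	GT:AD	0/1:59,47	0/1:53,101
chr1	48789	.	A	T	.	PASS	.	GT:AD	0/1:37,38	0/1:40,81
chr1	50294	.	A	T	.	PASS	.	GT:AD	0/1:51,56	0/1:27,36
chr1	52044	.	A	T	.	PASS	.	GT:AD	0/1:52,65	0/1:49,81
chr1	52333	.	A	T	.	PASS	.	GT:AD	0/1:39,53	0/1:17,39
chr1	52626	.	A	T	.	PASS	.	GT:AD	0/1:60,57	0/1:70,122
chr1	52890	.	A	T	.	PASS	.	GT:AD	0/1:38,30	0/1:21,52
chr1	53232	.	A	T	.	PASS	.	GT:AD	0/1:46,52	0/1:39,58
chr1	53367	.	A	T	.	PASS	.	GT:AD	0/1:35,31	0/1:27,39
chr1	53401	.	A	T	.	PASS	.	GT:AD	0/1:55,42	0/1:53,104
chr1	53451	.	A	T	.	PASS	.	GT:AD	0/1:40,35	0/1:31,52
chr1	53921	.	A	T	.	PASS	.	GT:AD	0/1:31,30	0/1:94,22
chr1	54036	.	A	T	.	PASS	.	GT:AD	0/1:22,34	0/1:26,59
chr1	54921	.	A	T	.	PASS	.	GT:AD	0/1:78,67	0/1:25,34
chr1	55197	.	A	T	.	PASS	.	GT:AD	0/1:37,88	0/1:44,77
chr1	55706	.	A	T	.	PASS	.	GT:AD	0/1:50,46	0/1:49,99
chr1	56281	.	A	T	.	PASS	.	GT:AD	0/1:35,40	0/1:22,47
chr1	56572	.	A	T	.	PASS	.	GT:AD	0/1:55,67	0/1:32,80
chr1	56625	.	A	T	.	PASS	.	GT:AD	0/1:55,44	0/1:55,84
chr1	58487	.	A	T	.	PASS	.	GT:AD	0/1:15,46	0/1:24,35
chr1	59202	.	A	T	.	PASS	.	GT:AD	0/1:40,42	0/1:27,58
chr1	59581	.	A	T	.	PASS	.	GT:AD	0/1:44,58	0/1:44,79
chr1	59668	.	A	T	.	PASS	.	GT:AD	0/1:43,56	0/1:35,75
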