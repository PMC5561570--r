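cpg_id	cpg_chrom	cpg_pos	gene	reported_frequency	snp_id	snp_pos	printed_distance
cg03636183	19	17000586	F2RL3	12	rs2227357	17003553	2967
cg05951221	2	233284402	2q37.1	8	rs790051	233282536	-1866
cg06126421	6	30720081	6p21.33	7	rs2535324	30718035	-2046
cg06126421	6	30720081	6p21.33	7	rs3095339	30727983	7902
cg06126421	6	30720081	6p21.33	7	rs3131036	30728290	8209
cg06126421	6	30720081	6p21.33	7	rs3094122	30728360	8279
cg06126421	6	30720081	6p21.33	7	rs13217914	30737552	17471
cg06126421	6	30720081	6p21.33	7	rs6911571	30739657	19576
cg06126421	6	30720081	6p21.33	7	rs4713361	30753639	33558
cg06126421	6	30720081	6p21.33	7	rs13201769	30756066	35985
cg03329539	2	233283329	2q37.1	6	rs790051	233282536	-793
cg03329539	2	233283329	2q37.1	6	rs34547337	233300755	17426
cg14817490	5	392920	AHRR	6	rs75509302	365653	-27267
cg14817490	5	392920	AHRR	6	rs11746079	410980	18060
cg14817490	5	392920	AHRR	6	rs72717419	431996	39076
cg14817490	5	392920	AHRR	6	rs2672725	434981	42061
cg23576855	5	373300	AHRR	NA	rs75509302	365653	-7647
cg11902777	5	368843	AHRR	NA	rs75509302	365653	-3190
cg17287155	5	393347	AHRR	NA	rs75509302	365653	-27694
cg03991871	5	368448	AHRR	NA	rs75509302	365653	-2795
cg12806681	5	368395	AHRR	NA	rs75509302	365653	-2742
cg23916896	5	368805	AHRR	NA	rs75509302	365653	-3152
cg03604011	5	400201	AHRR	NA	rs75509302	365653	-34548
cg10399789	1	92945668	GFI1	NA	rs34835481	92991624	45956
cg12876356	1	92946825	GFI1	NA	rs34835481	92991624	44799
cg09662411	1	92946132	GFI1	NA	rs34835481	92991624	45492
cg18146737	1	92946701	GFI1	NA	rs34835481	92991624	44923
cg18316974	1	92947035	GFI1	NA	rs34835481	92991624	44589
cg09935388	1	92947588	GFI1	NA	rs34835481	92991624	44036
cg12876356	1	92946825	GFI1	NA	rs79050605	92925962	-20863
cg18146737	1	92946701	GFI1	NA	rs79050605	92925962	-20739
cg18316974	1	92947035	GFI1	NA	rs79050605	92925962	-21073
cg09662411	1	92946132	GFI1	NA	rs79050605	92925962	-20170
cg09935388	1	92947588	GFI1	NA	rs79050605	92925962	-21626
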