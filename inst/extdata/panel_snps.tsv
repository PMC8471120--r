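# 39-SNP / 5-gene CYP pharmacogenetic panel definition (OpenArray TaqMan assays).
# One row per (rsID, alt base); tri-allelic sites span two rows. Base conventions follow
# the assay reporting strand. tagged_alleles: star alleles whose panel-level signature
# includes this alt base (per-base split of tri-allelic sites per PharmVar haplotype
# definitions). ancillary=TRUE marks the CYP3A5 H30Y component of the joint *3 assay:
# it is assayed and QC-counted but distinguishes a sub-allele below panel resolution,
# so it does not enter allele signatures.
gene	rsid	ref_base	alt_base	tagged_alleles	assay_id	variant_label	ancillary
CYP2B6	rs34223104	T	C	*22,*34,*35,*36	C__27830964_10	-82T>C	FALSE
CYP2B6	rs28399499	T	C	*16,*18	C__60732328_20	983T>C	FALSE
CYP2B6	rs3211371	C	T	*5,*7	C__30634242_40	25505C>T	FALSE
CYP2C19	rs12248560	C	T	*17	C____469857_10	-806C>T	FALSE
CYP2C19	rs28399504	A	G	*4	C__30634136_10	1A>G	FALSE
CYP2C19	rs41291556	T	C	*8	C__30634130_30	12711T>C	FALSE
CYP2C19	rs72552267	G	A	*6	C__27531918_10	12748G>A	FALSE
CYP2C19	rs17884712	G	A	*9	C__25745302_30	12784G>A	FALSE
CYP2C19	rs4986893	G	A	*3	C__27861809_10	17948G>A	FALSE
CYP2C19	rs6413438	C	T	*10	C__30634128_10	19153C>T	FALSE
CYP2C19	rs4244285	G	A	*2	C__25986767_70	19154G>A	FALSE
CYP2C19	rs72558186	T	A	*7	C__30634127_10	19294T>A	FALSE
CYP2C19	rs56337013	C	T	*5	C__27861810_10	90033C>T	FALSE
CYP2C9	rs1799853	C	T	*2,*35,*61	C__25625805_10	3608C>T	FALSE
CYP2C9	rs9332131	A	-	*6	C__32287221_20	10601delA	FALSE
CYP2C9	rs28371685	C	T	*11	C__30634132_70	42542C>T	FALSE
CYP2C9	rs1057910	A	C	*3,*18	C__27104892_10	42614A>C	FALSE
CYP2C9	rs56165452	T	C	*4	C__30634131_20	42615T>C	FALSE
CYP2C9	rs28371686	C	G	*5	C__27859817_40	42619C>G	FALSE
CYP2D6	rs1065852	C	T	*10,*36,*37,*47,*49,*52,*54,*57,*64,*65,*69,*72,*87,*94,*95,*99,*100,*101,*114,*132	C__11484460_40	100C>T	FALSE
CYP2D6	rs5030862	G	A	*12	C__27531552_A0	124G>A	FALSE
CYP2D6	rs28371706	C	T	*17,*40,*58,*64	C___2222771_A0	1022C>T	FALSE
CYP2D6	rs28371706	C	A	*82	C___2222771_A0	1022C>A	FALSE
CYP2D6	rs5030655	T	-	*6	C__32407243_20	1708delT	FALSE
CYP2D6	rs5030865	G	T	*8	C_30634117D_M0	1759G>T	FALSE
CYP2D6	rs5030865	G	A	*14,*114	C_30634117C_K0	1759G>A	FALSE
CYP2D6	rs3892097	G	A	*4	C__27102431_D0	1847G>A	FALSE
CYP2D6	rs35742686	A	-	*3	C__32407232_50	2550delA	FALSE
CYP2D6	rs5030867	A	C	*7	C__32388575_A0	2936A>C	FALSE
CYP2D6	rs28371725	G	A	*32,*41,*69,*91,*119,*123,*132,*138	C__34816116_20	2989G>A	FALSE
CYP2D6	rs59421388	G	A	*29,*70,*109	C__34816113_20	3184G>A	FALSE
CYP2D6	rs1135840	G	C	*2,*8,*10,*11,*12,*14,*17,*19,*20,*21,*28,*29,*30,*31,*32,*35,*36,*37,*39,*40,*41,*42,*45,*46,*47,*49,*51,*52,*54,*55,*56,*57,*58,*59,*64,*65,*69,*70,*72,*73,*83,*84,*85,*87,*88,*94,*95,*98,*99,*100,*101,*102,*103,*104,*105,*111,*114,*117,*121,*123,*125,*126,*128,*129,*132,*133,*135,*136,*138	C__27102414_10	4181G>C	FALSE
CYP2D6	rs16947	C	T	*2,*8,*11,*12,*14,*17,*19,*20,*21,*28,*29,*30,*31,*32,*34,*35,*40,*41,*42,*45,*46,*51,*55,*58,*59,*65,*69,*73,*84,*85,*91,*98,*102,*103,*104,*105,*111,*114,*117,*121,*123,*125,*126,*128,*129,*133,*135,*136,*138	C__27102425_10	2851C>T	FALSE
CYP2D6	rs5030656	CTT	-	*9,*109,*115	C__32407229_60	2616delAAG	FALSE
CYP3A5	rs55817950	C	T	*8	C__30633872_10	3699C>T	FALSE
CYP3A5	rs776746	A	G	*3	C__26201809_30	6986A>G	FALSE
CYP3A5	rs28383468	C	T	*3	C__30633871_50	3705C>T	TRUE
CYP3A5	rs10264272	G	A	*6	C__30203950_10	14690G>A	FALSE
CYP3A5	rs28383479	G	A	*9	C__30633863_10	19386G>A	FALSE
CYP3A5	rs41303343	-	T	*7	C__32287188_10	27131_27132insT	FALSE
CYP3A5	rs28365083	C	A	*2	C__30633862_10	27289C>A	FALSE
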