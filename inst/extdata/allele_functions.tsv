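# Allele function classes and activity values, compiled from CPIC/PharmVar allele
# functionality references. activity_value is on the {0, 0.5, 1} grid used by the
# CYP2D6 activity-score phenotype binning (NA where not established or not applicable);
# function_class=unknown yields an Indeterminate phenotype downstream. Alleles whose
# clinical function has not been assigned by the consortia are recorded as unknown
# rather than guessed.
gene	allele	function_class	activity_value
CYP2B6	*1	normal	1
CYP2B6	*5	normal	1
CYP2B6	*7	decreased	0.5
CYP2B6	*16	decreased	0.5
CYP2B6	*18	no_function	0
CYP2B6	*22	increased	NA
CYP2B6	*34	unknown	NA
CYP2B6	*35	unknown	NA
CYP2B6	*36	unknown	NA
CYP2C19	*1	normal	1
CYP2C19	*2	no_function	0
CYP2C19	*3	no_function	0
CYP2C19	*4	no_function	0
CYP2C19	*5	no_function	0
CYP2C19	*6	no_function	0
CYP2C19	*7	no_function	0
CYP2C19	*8	no_function	0
CYP2C19	*9	decreased	0.5
CYP2C19	*10	decreased	0.5
CYP2C19	*17	increased	NA
CYP2C9	*1	normal	1
CYP2C9	*2	decreased	0.5
CYP2C9	*3	no_function	0
CYP2C9	*4	decreased	0.5
CYP2C9	*5	no_function	0
CYP2C9	*6	no_function	0
CYP2C9	*11	decreased	0.5
CYP2C9	*18	no_function	0
CYP2C9	*35	unknown	NA
CYP2C9	*61	unknown	NA
CYP2D6	*1	normal	1
CYP2D6	*2	normal	1
CYP2D6	*3	no_function	0
CYP2D6	*4	no_function	0
CYP2D6	*5	no_function	0
CYP2D6	*6	no_function	0
CYP2D6	*7	no_function	0
CYP2D6	*8	no_function	0
CYP2D6	*9	decreased	0.5
CYP2D6	*10	decreased	0.5
CYP2D6	*11	no_function	0
CYP2D6	*12	no_function	0
CYP2D6	*14	decreased	0.5
CYP2D6	*17	decreased	0.5
CYP2D6	*19	no_function	0
CYP2D6	*20	no_function	0
CYP2D6	*21	no_function	0
CYP2D6	*28	unknown	NA
CYP2D6	*29	decreased	0.5
CYP2D6	*30	unknown	NA
CYP2D6	*31	no_function	0
CYP2D6	*32	unknown	NA
CYP2D6	*34	normal	1
CYP2D6	*35	normal	1
CYP2D6	*36	no_function	0
CYP2D6	*37	unknown	NA
CYP2D6	*39	normal	1
CYP2D6	*40	no_function	0
CYP2D6	*41	decreased	0.5
CYP2D6	*42	no_function	0
CYP2D6	*45	normal	1
CYP2D6	*46	normal	1
CYP2D6	*47	no_function	0
CYP2D6	*49	decreased	0.5
CYP2D6	*51	no_function	0
CYP2D6	*52	unknown	NA
CYP2D6	*54	decreased	0.5
CYP2D6	*55	unknown	NA
CYP2D6	*56	no_function	0
CYP2D6	*57	no_function	0
CYP2D6	*58	unknown	NA
CYP2D6	*59	decreased	0.5
CYP2D6	*64	unknown	NA
CYP2D6	*65	unknown	NA
CYP2D6	*69	no_function	0
CYP2D6	*70	unknown	NA
CYP2D6	*72	unknown	NA
CYP2D6	*73	unknown	NA
CYP2D6	*82	unknown	NA
CYP2D6	*83	unknown	NA
CYP2D6	*84	unknown	NA
CYP2D6	*85	unknown	NA
CYP2D6	*87	unknown	NA
CYP2D6	*88	unknown	NA
CYP2D6	*91	unknown	NA
CYP2D6	*94	unknown	NA
CYP2D6	*95	unknown	NA
CYP2D6	*98	unknown	NA
CYP2D6	*99	no_function	0
CYP2D6	*100	no_function	0
CYP2D6	*101	unknown	NA
CYP2D6	*102	unknown	NA
CYP2D6	*103	unknown	NA
CYP2D6	*104	unknown	NA
CYP2D6	*105	unknown	NA
CYP2D6	*109	unknown	NA
CYP2D6	*111	unknown	NA
CYP2D6	*114	unknown	NA
CYP2D6	*115	unknown	NA
CYP2D6	*117	unknown	NA
CYP2D6	*119	unknown	NA
CYP2D6	*121	unknown	NA
CYP2D6	*123	unknown	NA
CYP2D6	*125	unknown	NA
CYP2D6	*126	unknown	NA
CYP2D6	*128	unknown	NA
CYP2D6	*129	unknown	NA
CYP2D6	*132	unknown	NA
CYP2D6	*133	unknown	NA
CYP2D6	*135	unknown	NA
CYP2D6	*136	unknown	NA
CYP2D6	*138	unknown	NA
CYP3A5	*1	normal	1
CYP3A5	*2	unknown	NA
CYP3A5	*3	no_function	0
CYP3A5	*6	no_function	0
CYP3A5	*7	no_function	0
CYP3A5	*8	unknown	NA
CYP3A5	*9	unknown	NA
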