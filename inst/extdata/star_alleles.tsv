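# Star-allele inventory per gene, mirroring the detectable-allele lists of the
# published 39-SNP panel. callable=FALSE marks alleles listed in the inventory but not
# assayable from the panel's SNPs (CYP2D6 *5 whole-gene deletion: no copy-number assay).
gene	allele	callable
CYP2B6	*1	TRUE
CYP2B6	*5	TRUE
CYP2B6	*7	TRUE
CYP2B6	*16	TRUE
CYP2B6	*18	TRUE
CYP2B6	*22	TRUE
CYP2B6	*34	TRUE
CYP2B6	*35	TRUE
CYP2B6	*36	TRUE
CYP2C19	*1	TRUE
CYP2C19	*2	TRUE
CYP2C19	*3	TRUE
CYP2C19	*4	TRUE
CYP2C19	*5	TRUE
CYP2C19	*6	TRUE
CYP2C19	*7	TRUE
CYP2C19	*8	TRUE
CYP2C19	*9	TRUE
CYP2C19	*10	TRUE
CYP2C19	*17	TRUE
CYP2C9	*1	TRUE
CYP2C9	*2	TRUE
CYP2C9	*3	TRUE
CYP2C9	*4	TRUE
CYP2C9	*5	TRUE
CYP2C9	*6	TRUE
CYP2C9	*11	TRUE
CYP2C9	*18	TRUE
CYP2C9	*35	TRUE
CYP2C9	*61	TRUE
CYP2D6	*1	TRUE
CYP2D6	*2	TRUE
CYP2D6	*3	TRUE
CYP2D6	*4	TRUE
CYP2D6	*5	FALSE
CYP2D6	*6	TRUE
CYP2D6	*7	TRUE
CYP2D6	*8	TRUE
CYP2D6	*9	TRUE
CYP2D6	*10	TRUE
CYP2D6	*11	TRUE
CYP2D6	*12	TRUE
CYP2D6	*14	TRUE
CYP2D6	*17	TRUE
CYP2D6	*19	TRUE
CYP2D6	*20	TRUE
CYP2D6	*21	TRUE
CYP2D6	*28	TRUE
CYP2D6	*29	TRUE
CYP2D6	*30	TRUE
CYP2D6	*31	TRUE
CYP2D6	*32	TRUE
CYP2D6	*34	TRUE
CYP2D6	*35	TRUE
CYP2D6	*36	TRUE
CYP2D6	*37	TRUE
CYP2D6	*39	TRUE
CYP2D6	*40	TRUE
CYP2D6	*41	TRUE
CYP2D6	*42	TRUE
CYP2D6	*45	TRUE
CYP2D6	*46	TRUE
CYP2D6	*47	TRUE
CYP2D6	*49	TRUE
CYP2D6	*51	TRUE
CYP2D6	*52	TRUE
CYP2D6	*54	TRUE
CYP2D6	*55	TRUE
CYP2D6	*56	TRUE
CYP2D6	*57	TRUE
CYP2D6	*58	TRUE
CYP2D6	*59	TRUE
CYP2D6	*64	TRUE
CYP2D6	*65	TRUE
CYP2D6	*69	TRUE
CYP2D6	*70	TRUE
CYP2D6	*72	TRUE
CYP2D6	*73	TRUE
CYP2D6	*82	TRUE
CYP2D6	*83	TRUE
CYP2D6	*84	TRUE
CYP2D6	*85	TRUE
CYP2D6	*87	TRUE
CYP2D6	*88	TRUE
CYP2D6	*91	TRUE
CYP2D6	*94	TRUE
CYP2D6	*95	TRUE
CYP2D6	*98	TRUE
CYP2D6	*99	TRUE
CYP2D6	*100	TRUE
CYP2D6	*101	TRUE
CYP2D6	*102	TRUE
CYP2D6	*103	TRUE
CYP2D6	*104	TRUE
CYP2D6	*105	TRUE
CYP2D6	*109	TRUE
CYP2D6	*111	TRUE
CYP2D6	*114	TRUE
CYP2D6	*115	TRUE
CYP2D6	*117	TRUE
CYP2D6	*119	TRUE
CYP2D6	*121	TRUE
CYP2D6	*123	TRUE
CYP2D6	*125	TRUE
CYP2D6	*126	TRUE
CYP2D6	*128	TRUE
CYP2D6	*129	TRUE
CYP2D6	*132	TRUE
CYP2D6	*133	TRUE
CYP2D6	*135	TRUE
CYP2D6	*136	TRUE
CYP2D6	*138	TRUE
CYP3A5	*1	TRUE
CYP3A5	*2	TRUE
CYP3A5	*3	TRUE
CYP3A5	*6	TRUE
CYP3A5	*7	TRUE
CYP3A5	*8	TRUE
CYP3A5	*9	TRUE
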