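# Per-allele population frequencies (fractions), compiled from CPIC/PharmGKB
# population summaries for the nine biogeographic groups used in panel reporting.
# SSA=Sub-Saharan African, AA/AC=African American/Afro-Caribbean, Eur=European,
# NE=Near Eastern, EA=East Asian, CSA=Central/South Asian, Ame=American, Lat=Latino,
# Oce=Oceanian. NA = no published estimate: such alleles are floored at eps=1e-6 when
# the panel is loaded, so they rank below all observed alleles but remain reportable.
# *1 is never listed here; its frequency is derived as 1 - sum(other alleles) per
# gene and population.
gene	allele	SSA	AA/AC	Eur	NE	EA	CSA	Ame	Lat	Oce
CYP2B6	*5	0.02	0.05	0.11	0.10	0.01	0.05	0.03	0.07	0.01
CYP2B6	*7	0.005	0.005	0.01	0.005	0.005	0.005	0.005	0.005	0.005
CYP2B6	*16	0.07	0.04	NA	NA	NA	NA	NA	NA	NA
CYP2B6	*18	0.05	0.03	NA	NA	NA	NA	NA	0.01	NA
CYP2B6	*22	0.01	0.01	0.02	0.02	0.01	0.02	NA	0.02	NA
CYP2C19	*2	0.15	0.18	0.15	0.12	0.31	0.30	0.10	0.13	0.61
CYP2C19	*3	0.003	0.003	0.004	0.02	0.06	0.01	0.002	0.002	0.15
CYP2C19	*4	NA	0.001	0.002	0.002	NA	0.002	NA	0.001	NA
CYP2C19	*5	NA	NA	NA	NA	0.001	NA	NA	NA	NA
CYP2C19	*6	NA	NA	0.0005	NA	NA	NA	NA	NA	NA
CYP2C19	*8	NA	NA	0.003	0.002	NA	NA	NA	NA	NA
CYP2C19	*9	0.012	0.007	NA	NA	NA	NA	NA	NA	NA
CYP2C19	*10	0.002	0.002	NA	NA	NA	NA	NA	NA	NA
CYP2C19	*17	0.16	0.19	0.22	0.22	0.015	0.16	0.12	0.12	0.002
CYP2C9	*2	0.01	0.03	0.125	0.12	0.001	0.05	0.06	0.07	0.005
CYP2C9	*3	0.005	0.01	0.07	0.10	0.034	0.10	0.04	0.04	0.002
CYP2C9	*4	NA	NA	NA	NA	0.0005	NA	NA	NA	NA
CYP2C9	*5	0.006	0.01	NA	NA	NA	NA	NA	NA	NA
CYP2C9	*6	0.003	0.007	NA	NA	NA	NA	NA	NA	NA
CYP2C9	*11	0.02	0.02	0.002	NA	NA	NA	NA	NA	NA
CYP2C9	*18	NA	NA	NA	NA	NA	0.002	NA	NA	NA
CYP2D6	*2	0.20	0.18	0.27	0.22	0.13	0.27	0.20	0.22	0.10
CYP2D6	*3	NA	0.003	0.015	0.003	NA	NA	0.002	0.005	NA
CYP2D6	*4	0.03	0.06	0.185	0.12	0.004	0.10	0.03	0.10	0.02
CYP2D6	*6	NA	0.002	0.01	0.003	NA	NA	NA	NA	NA
CYP2D6	*7	NA	NA	NA	0.001	NA	NA	NA	NA	NA
CYP2D6	*8	NA	0.001	NA	NA	NA	NA	NA	NA	NA
CYP2D6	*9	NA	0.005	0.025	0.01	NA	NA	NA	0.01	NA
CYP2D6	*10	0.05	0.08	0.015	0.04	0.42	0.06	0.02	0.02	0.02
CYP2D6	*14	NA	NA	NA	NA	0.002	NA	NA	NA	NA
CYP2D6	*17	0.19	0.15	0.003	0.005	0.0005	0.003	0.005	0.01	0.002
CYP2D6	*29	0.09	0.06	NA	0.005	NA	NA	NA	0.005	NA
CYP2D6	*35	NA	0.01	0.05	0.02	NA	NA	NA	0.02	NA
CYP2D6	*36	0.005	NA	NA	NA	0.02	NA	NA	NA	NA
CYP2D6	*39	0.01	0.01	NA	NA	0.03	NA	NA	NA	NA
CYP2D6	*41	0.06	0.05	0.09	0.14	0.02	0.11	0.02	0.03	0.01
CYP2D6	*45	0.05	0.05	NA	NA	NA	NA	NA	NA	NA
CYP2D6	*46	0.01	0.01	NA	NA	NA	NA	NA	NA	NA
CYP3A5	*2	NA	NA	0.002	NA	NA	NA	NA	NA	NA
CYP3A5	*3	0.33	0.45	0.92	0.87	0.73	0.66	0.78	0.77	0.92
CYP3A5	*6	0.10	0.08	0.003	0.02	NA	NA	NA	0.02	NA
CYP3A5	*7	0.10	0.06	NA	NA	NA	NA	NA	0.01	NA
CYP3A5	*8	0.003	NA	NA	NA	NA	NA	NA	NA	NA
CYP3A5	*9	NA	NA	NA	NA	0.002	NA	NA	NA	NA
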