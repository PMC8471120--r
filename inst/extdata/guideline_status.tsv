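# Guideline coverage (CPIC, DPWG) and drug-label pharmacogenetic flags (FDA,
# EMA/AIFA) per drug, as transcribed from the published comparison table. One row
# per drug-gene pair for guideline-covered drugs; a single row with empty gene for
# drugs with no recommendation in either guideline. noRec = no recommendation
# reported in the guideline. Label flags: Y = label reports CYP phenotype
# information, N = none, NA = drug not approved by that agency, empty = not stated.
# Label flags are metadata only and take no part in recommendation logic.
drug	gene	cpic	dpwg	fda_label	ema_aifa_label
Agomelatine		noRec	noRec		
Alprazolam		noRec	noRec		
Amitriptyline	CYP2D6	has_recommendation	has_recommendation	Y	Y
Amitriptyline	CYP2C19	has_recommendation	has_recommendation	N	Y
Aripiprazole	CYP2D6	has_recommendation	has_recommendation	Y	Y
Atomoxetine	CYP2D6	has_recommendation	has_recommendation	Y	Y
Bupropion		noRec	noRec		
Buspirone		noRec	noRec		NA
Carbamazepine		noRec	noRec		
Chlorpromazine		noRec	noRec		
Citalopram	CYP2C19	has_recommendation	has_recommendation	Y	Y
Clobazam	CYP2C19	has_recommendation	has_recommendation	Y	Y
Clomipramine	CYP2D6	has_recommendation	has_recommendation	Y	Y
Clonazepam		noRec	noRec		
Clopidogrel	CYP2C19	has_recommendation	has_recommendation	Y	Y
Clozapine		noRec	noRec		
Desipramine		noRec	noRec		NA
Desvenlafaxine		noRec	noRec		NA
Doxepin	CYP2D6	has_recommendation	has_recommendation	Y	NA
Doxepin	CYP2C19	has_recommendation	has_recommendation	N	NA
Duloxetine		noRec	noRec		
Escitalopram	CYP2C19	has_recommendation	has_recommendation	Y	Y
Fluoxetine	CYP2D6	has_recommendation	has_recommendation	Y	Y
Fluvoxamine	CYP2D6	has_recommendation	has_recommendation	Y	N
Haloperidol	CYP2D6	has_recommendation	has_recommendation	N	N
Imipramine	CYP2D6	has_recommendation	has_recommendation	Y	NA
Imipramine	CYP2C19	has_recommendation	has_recommendation	N	NA
Lurasidone		noRec	noRec		
Mirtazapine		noRec	noRec		
Nortriptyline	CYP2D6	has_recommendation	has_recommendation	Y	N
Olanzapine		noRec	noRec		
Oxcarbazepine		noRec	noRec		
Paroxetine	CYP2D6	has_recommendation	has_recommendation	Y	Y
Perphenazine		noRec	noRec		
Phenytoin	CYP2C9	has_recommendation	has_recommendation	Y	Y
Pimozide	CYP2D6	has_recommendation	has_recommendation	N	N
Quetiapine		noRec	noRec		
Reboxetine		noRec	noRec		
Risperidone		noRec	noRec		
Sertraline	CYP2C19	has_recommendation	has_recommendation	N	Y
Thioridazine		noRec	noRec		NA
Trazodone		noRec	noRec		
Trimipramine	CYP2C19	has_recommendation	has_recommendation	Y	Y
Valproic acid		noRec	noRec		
Venlafaxine		noRec	noRec		
Vortioxetine		noRec	noRec		NA
Ziprasidone		noRec	noRec		
Zolpidem		noRec	noRec		
Zonisamide		noRec	noRec		
Zuclopenthixol		noRec	noRec		
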