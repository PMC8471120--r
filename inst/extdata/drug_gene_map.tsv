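# Drug-to-CYP-gene map for the neuropsychiatric drug list (46 neuropsychiatric drugs
# plus clopidogrel as transcribed; the source text announces 47 + clopidogrel but its
# printed table holds 47 rows in total). actionable_genes: genes whose genotype
# carries a guideline dosing recommendation for the drug. metabolism_genes: genes
# associated with the drug's metabolism but not covered by a guideline; carried as
# metadata only (several lie outside the 5-gene panel). Semicolon-separated;
# empty = none.
drug	actionable_genes	metabolism_genes
Agomelatine		CYP1A2;CYP2C9
Alprazolam		CYP2C19;CYP2C9;CYP3A4;CYP3A5;CYP3A7
Amitriptyline	CYP2D6;CYP2C19	CYP1A2;CYP2C9;CYP3A4
Aripiprazole	CYP2D6	CYP3A4
Atomoxetine	CYP2D6	CYP2C19
Bupropion		CYP2B6
Buspirone		CYP3A4
Carbamazepine		CYP1A2;CYP3A4;CYP3A5;CYP2C19;CYP2C8
Chlorpromazine		CYP2D6;CYP2C19;CYP1A2;CYP3A4
Citalopram	CYP2C19	CYP2D6;CYP3A4
Clobazam	CYP2C19	CYP3A;CYP2B6
Clomipramine	CYP2D6	CYP2C19;CYP1A2;CYP3A4
Clonazepam		CYP3A4;CYP3A5
Clopidogrel	CYP2C19	
Clozapine		CYP1A2;CYP2D6;CYP3A4;CYP2C19
Desipramine		CYP1A2;CYP2D6
Desvenlafaxine		CYP2C19;CYP3A4
Doxepin	CYP2D6;CYP2C19	CYP2C9
Duloxetine		CYP1A2;CYP2D6
Escitalopram	CYP2C19	CYP2D6;CYP3A4
Fluoxetine	CYP2D6	CYP1A2;CYP2B6;CYP2C9;CYP2C19;CYP3A4;CYP3A5
Fluvoxamine	CYP2D6	CYP1A2
Haloperidol	CYP2D6	CYP3A4
Imipramine	CYP2D6;CYP2C19	CYP1A2;CYP3A4
Lurasidone		CYP3A4
Mirtazapine		CYP1A2;CYP2D6;CYP3A4;CYP2C19
Nortriptyline	CYP2D6	CYP1A2;CYP2C19;CYP3A4
Olanzapine		CYP1A2;CYP2D6
Oxcarbazepine		
Paroxetine	CYP2D6	CYP3A4
Perphenazine		CYP2D6
Phenytoin	CYP2C9	CYP2C19
Pimozide	CYP2D6	CYP3A4;CYP1A2
Quetiapine		CYP2D6;CYP3A4
Reboxetine		CYP3A4
Risperidone		CYP2D6
Sertraline	CYP2C19	CYP2B6;CYP2C9;CYP2D6;CYP3A4
Thioridazine		CYP2D6
Trazodone		CYP2D6;CYP3A4;CYP1A2
Trimipramine	CYP2C19	CYP2C9;CYP2D6;CYP3A4
Valproic acid		CYP2A6;CYP2B6;CYP2C9;CYP2C19
Venlafaxine		CYP2C19;CYP2D6;CYP3A4
Vortioxetine		CYP3A4;CYP2C9;CYP2D6;CYP2C19
Ziprasidone		CYP3A4
Zolpidem		CYP1A2;CYP2D6;CYP3A4
Zonisamide		CYP3A4;CYP2C19
Zuclopenthixol		CYP2D6;CYP3A4
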