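Sample	Gene	rsID	Genotype
S001	CYP2B6	rs34223104	T/T
S001	CYP2B6	rs28399499	T/T
S001	CYP2B6	rs3211371	C/C
S001	CYP2C19	rs12248560	C/C
S001	CYP2C19	rs28399504	A/A
S001	CYP2C19	rs41291556	T/T
S001	CYP2C19	rs72552267	G/G
S001	CYP2C19	rs17884712	G/G
S001	CYP2C19	rs4986893	G/G
S001	CYP2C19	rs6413438	C/C
S001	CYP2C19	rs4244285	G/G
S001	CYP2C19	rs72558186	T/T
S001	CYP2C19	rs56337013	C/C
S001	CYP2C9	rs1799853	C/C
S001	CYP2C9	rs9332131	A/A
S001	CYP2C9	rs28371685	C/C
S001	CYP2C9	rs1057910	A/A
S001	CYP2C9	rs56165452	T/T
S001	CYP2C9	rs28371686	C/C
S001	CYP2D6	rs1065852	C/C
S001	CYP2D6	rs5030862	G/G
S001	CYP2D6	rs28371706	C/C
S001	CYP2D6	rs5030655	T/T
S001	CYP2D6	rs5030865	G/G
S001	CYP2D6	rs3892097	G/G
S001	CYP2D6	rs35742686	A/A
S001	CYP2D6	rs5030867	A/A
S001	CYP2D6	rs28371725	G/G
S001	CYP2D6	rs59421388	G/G
S001	CYP2D6	rs1135840	C/G
S001	CYP2D6	rs16947	C/T
S001	CYP2D6	rs5030656	CTT/CTT
S001	CYP3A5	rs55817950	C/C
S001	CYP3A5	rs776746	G/G
S001	CYP3A5	rs28383468	C/C
S001	CYP3A5	rs10264272	G/G
S001	CYP3A5	rs28383479	G/G
S001	CYP3A5	rs41303343	-/-
S001	CYP3A5	rs28365083	C/C
S002	CYP2B6	rs34223104	C/T
S002	CYP2B6	rs28399499	
S002	CYP2B6	rs3211371	C/C
S002	CYP2C19	rs12248560	C/T
S002	CYP2C19	rs28399504	A/A
S002	CYP2C19	rs41291556	
S002	CYP2C19	rs72552267	G/G
S002	CYP2C19	rs17884712	G/G
S002	CYP2C19	rs4986893	G/G
S002	CYP2C19	rs6413438	C/C
S002	CYP2C19	rs4244285	G/G
S002	CYP2C19	rs72558186	T/T
S002	CYP2C19	rs56337013	C/C
S002	CYP2C9	rs1799853	C/C
S002	CYP2C9	rs9332131	A/A
S002	CYP2C9	rs28371685	C/C
S002	CYP2C9	rs1057910	A/A
S002	CYP2C9	rs56165452	T/T
S002	CYP2C9	rs28371686	C/C
S002	CYP2D6	rs1065852	C/C
S002	CYP2D6	rs5030862	G/G
S002	CYP2D6	rs28371706	C/C
S002	CYP2D6	rs5030655	T/T
S002	CYP2D6	rs5030865	G/G
S002	CYP2D6	rs3892097	
S002	CYP2D6	rs35742686	A/A
S002	CYP2D6	rs5030867	
S002	CYP2D6	rs28371725	G/G
S002	CYP2D6	rs59421388	
S002	CYP2D6	rs1135840	G/G
S002	CYP2D6	rs16947	C/C
S002	CYP2D6	rs5030656	CTT/CTT
S002	CYP3A5	rs55817950	C/C
S002	CYP3A5	rs776746	A/G
S002	CYP3A5	rs28383468	C/C
S002	CYP3A5	rs10264272	G/G
S002	CYP3A5	rs28383479	G/G
S002	CYP3A5	rs41303343	-/-
S002	CYP3A5	rs28365083	C/C
S003	CYP2B6	rs34223104	T/T
S003	CYP2B6	rs28399499	T/T
S003	CYP2B6	rs3211371	C/C
S003	CYP2C19	rs12248560	C/C
S003	CYP2C19	rs28399504	A/A
S003	CYP2C19	rs41291556	T/T
S003	CYP2C19	rs72552267	G/G
S003	CYP2C19	rs17884712	G/G
S003	CYP2C19	rs4986893	G/G
S003	CYP2C19	rs6413438	C/C
S003	CYP2C19	rs4244285	G/G
S003	CYP2C19	rs72558186	T/T
S003	CYP2C19	rs56337013	C/C
S003	CYP2C9	rs1799853	C/C
S003	CYP2C9	rs9332131	A/A
S003	CYP2C9	rs28371685	C/C
S003	CYP2C9	rs1057910	A/A
S003	CYP2C9	rs56165452	T/T
S003	CYP2C9	rs28371686	C/C
S003	CYP2D6	rs1065852	C/C
S003	CYP2D6	rs5030862	G/G
S003	CYP2D6	rs28371706	C/C
S003	CYP2D6	rs5030655	T/T
S003	CYP2D6	rs5030865	G/G
S003	CYP2D6	rs3892097	A/G
S003	CYP2D6	rs35742686	A/A
S003	CYP2D6	rs5030867	A/A
S003	CYP2D6	rs28371725	G/G
S003	CYP2D6	rs59421388	G/G
S003	CYP2D6	rs1135840	C/G
S003	CYP2D6	rs16947	C/T
S003	CYP2D6	rs5030656	CTT/CTT
S003	CYP3A5	rs55817950	C/C
S003	CYP3A5	rs776746	G/G
S003	CYP3A5	rs28383468	C/C
S003	CYP3A5	rs10264272	G/G
S003	CYP3A5	rs28383479	G/G
S003	CYP3A5	rs41303343	-/-
S003	CYP3A5	rs28365083	C/C
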