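# CYP2D6 activity-score phenotype bins (CPIC consensus; version tag reported in
# output). Score = sum of the two alleles' activity values. Interval is
# lower <= score <= upper; bins are disjoint and cover [0, Inf).
version	lower	upper	phenotype
cpic-2023	0	0	Poor Metabolizer
cpic-2023	0.25	1	Intermediate Metabolizer
cpic-2023	1.25	2.25	Normal Metabolizer
cpic-2023	2.5	Inf	Ultrarapid Metabolizer
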