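# Metabolizer phenotype lookup by unordered pair of allele function classes
# (CPIC-derived). Used for all panel genes except CYP2D6, which is binned by
# activity score (see cyp2d6_activity_bins.tsv). Pairs involving an allele of
# unknown function are Indeterminate and are handled in code, not listed here.
# Genes whose inventory has no increased-function allele can never reach the
# Rapid/Ultrarapid rows.
function_1	function_2	phenotype
normal	normal	Normal Metabolizer
normal	decreased	Intermediate Metabolizer
normal	no_function	Intermediate Metabolizer
decreased	decreased	Intermediate Metabolizer
decreased	no_function	Intermediate Metabolizer
no_function	no_function	Poor Metabolizer
increased	increased	Ultrarapid Metabolizer
increased	normal	Rapid Metabolizer
increased	decreased	Intermediate Metabolizer
increased	no_function	Intermediate Metabolizer
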