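# Phenoconversion (drug-interaction) rules: each row shifts the effective
# metabolizer phenotype of `gene` by `shift` steps on the ordered scale
# PM < IM < NM < RM < UM (negative = inhibition, positive = induction), clamped at
# the ends, whenever `drug` is among a subject's co-medications. Shipped EMPTY by
# design: with no rules the adjustment is the identity. Users may supply their own
# curated table.
drug	gene	shift
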