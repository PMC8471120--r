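# cypstar

Star-allele diplotype calling and drug-guideline annotation for a 39-SNP,
5-gene CYP pharmacogenetic panel.

## The problem

Psychiatric and neurological pharmacotherapy is dominated by drugs cleared
through a handful of polymorphic cytochrome P450 enzymes. Genotyping a small,
well-chosen SNP panel — here 39 SNPs across *CYP2B6*, *CYP2C19*, *CYP2C9*,
*CYP2D6* and *CYP3A5* — is enough to recognise the common star alleles
(\*1, \*2, …: named haplotypes defined by characteristic variant sets) of
each gene. But genotypes come **unphased**: a sample that is heterozygous at
two SNPs could carry both variants on one chromosome or one on each, and in
general many star-allele pairs (diplotypes) are consistent with the observed
base pairs. `cypstar` solves exactly this interpretation step, for laboratory
genotyping output in a plain 4-column table (`Sample, Gene, rsID, Genotype`).

## The method

For each gene, every catalogued star allele is reduced to its *panel
signature*: the set of assayed SNPs whose tag list contains it, each with a
required alternate base; \*1 is the reference haplotype with an empty
signature. A candidate diplotype (a₁, a₂) is **consistent** with a sample
when, at every non-missing SNP, the unordered pair of bases contributed by
the two haplotypes (alt where the SNP is in the allele's signature,
reference elsewhere) equals the observed base pair. Missing SNPs impose no
constraint, so incomplete data widen — never corrupt — the candidate set.

All n(n+1)/2 unordered allele pairs are scanned per gene (3,321 for
CYP2D6's 81 callable alleles; the cross-gene product space exceeds 15
billion combinations and is never enumerated). Candidates are ranked by
Hardy–Weinberg probability in a chosen reference population — f₁² for
homozygotes, 2·f₁·f₂ for heterozygotes, with bundled per-allele population
frequencies — and the top candidate is flagged. Diplotypes then map to
metabolizer phenotypes (Poor / Intermediate / Normal / Rapid / Ultrarapid,
or Indeterminate when an allele's function is unknown): CYP2D6 via
activity-score binning, the other genes via a function-class pair lookup.
Finally, phenotypes join a bundled 47-drug table with CPIC and DPWG
guideline-status flags to report which drugs carry an actionable dosing
recommendation for the sample.

A genotyping call-rate QC step (fraction of the 39 SNPs called; pass at
>90%) and a truth-known cohort simulator (Hardy–Weinberg sampling, rendered
through the same input format, with configurable no-call rate) round out the
toolkit.

## Worked example

A sample heterozygous at both rs4244285 (tags CYP2C19\*2) and rs12248560
(tags CYP2C19\*17), reference elsewhere:

```r
library(cypstar)
panel <- loadPanel()

tab <- data.frame(Sample = "PT01", Gene = "CYP2C19",
                  rsID = c("rs4244285", "rs12248560"),
                  Genotype = c("G/A", "C/T"))
sg <- parseGenotypeTable(tab, panel)[[1]]
enumerateDiplotypes(sg, "CYP2C19", panel, population = "Eur")
#> GeneDiplotypes: PT01 / CYP2C19 [called, population Eur]
#>   1 candidate diplotype(s)
#>    * *2/*17     p = 0.066
```

No catalogued allele carries both variants, so they must lie in *trans*: the
only consistent diplotype is \*2/\*17, with Hardy–Weinberg probability
2 × 0.15 × 0.22 = 0.066 in the European reference population. One
no-function plus one increased-function allele gives an Intermediate
Metabolizer, which is guideline-actionable for CYP2C19 substrates:

```r
callPhenotype("CYP2C19", c("*2", "*17"), panel)
#>      gene diplotype                phenotype activity_score
#> 1 CYP2C19    *2/*17 Intermediate Metabolizer             NA

ph <- phenotypeTable(callDiplotypes(list(sg), panel), panel)
lookupRecommendations(ph, panel, guideline = "CPIC",
                      drugs = c("Citalopram", "Sertraline", "Olanzapine")
                      )[, c("drug", "gene", "phenotype", "status")]
#>         drug    gene                phenotype            status
#> 1 Citalopram CYP2C19 Intermediate Metabolizer        actionable
#> 2 Olanzapine    <NA>                     <NA> no_recommendation
#> 3 Sertraline CYP2C19 Intermediate Metabolizer        actionable
```

The full pipeline (`runPipeline()`, or the CLI in
`inst/scripts/cypstar-cli.R` with subcommands `call`, `simulate`,
`validate`) writes per-cohort TSV reports plus a canonical JSON report:
input genotypes, call-rate QC, all candidate diplotypes, per-gene
phenotypes, rare (non-top) diplotypes, and the drug recommendation table
partitioned into actionable vs no-recommendation panels. A simulated
example cohort ships in `inst/extdata/example_genotypes.tsv`.

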