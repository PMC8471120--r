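---
title: "Calling CYP star-allele diplotypes from unphased panel genotypes"
author: "cypstar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CYP star-allele diplotypes from unphased panel genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypstar)
```

## The inference problem

A targeted pharmacogenetic panel observes, per sample, an unordered base
pair at each of 39 SNPs spread over five CYP genes. Clinical interpretation,
however, is written in terms of *star alleles* — named haplotypes (\*1,
\*2, ...) defined by characteristic variant combinations — and of
*diplotypes*, the unordered pair of star alleles a person carries at one
gene. Because panel genotypes are unphased and incomplete, a single
genotype vector is generally compatible with several diplotypes. `cypstar`
makes that ambiguity explicit: it enumerates **every** catalogued diplotype
consistent with the data, ranks the candidates by population frequency, and
carries the whole set (not just the winner) into the report.

## Allele model and consistency

Each star allele is reduced to its *panel signature*: the map from tag SNPs
to required alternate bases, obtained by inverting the panel's SNP table
(each assayed variant lists the alleles it tags). \*1, the reference
haplotype, has an empty signature. An allele contributes its alt base at
signature SNPs and the reference base everywhere else; a pair (a₁, a₂) is
consistent with a sample iff at every non-missing SNP of the gene the
multiset of contributed bases equals the observed base pair.

Three consequences of this **closed-world, exact-match** semantics are worth
stating plainly:

* A genotype that matches no catalogued pair yields an explicit `no_call`
  with the constraining rsIDs as diagnostics — never a forced nearest match.
  Novel-allele inference is out of scope.
* Homozygous-reference data call \*1/\*1 uniquely; they are evidence for
  the reference diplotype, not absence of evidence.
* Missingness only relaxes constraints: masking a SNP can only grow the
  candidate set (a property the test suite checks exhaustively), and a gene
  with no data at all is reported `unconstrained` with all n(n+1)/2 pairs.

Two representation choices depart from a naive transcription of the panel
table. First, alleles that the panel cannot distinguish (sub-alleles sharing
one panel signature, e.g. the many CYP2D6 alleles tagged only by
rs16947 + rs1135840) are **kept as distinct candidates** rather than
collapsed to a representative: the full catalogued inventory (81 callable
CYP2D6 alleles, 3,321 pairs) is scanned, equivalent alleles co-appear, and
frequency ranking separates them. This keeps the candidate list faithful to
the nomenclature at the cost of listing panel-indistinguishable alleles
side by side. Second, the CYP3A5 H30Y variant (rs28383468), assayed jointly
with rs776746 for a \*3 sub-variant, is counted and QC'd as a panel SNP but
flagged *ancillary* and excluded from signatures: making it a defining
variant of \*3 would mis-call every ordinary \*3 carrier, since the
sub-allele it distinguishes lies below panel resolution.

CYP2D6 \*5 (whole-gene deletion) and duplications are inventoried but not
callable — the panel has no copy-number assay — and are documented as a
panel limitation rather than silently dropped.

## Frequencies and ranking

Candidates are ranked by Hardy–Weinberg probability in a chosen reference
population: f² for homozygous pairs, 2f₁f₂ for heterozygous ones. The
bundled per-allele frequencies cover nine biogeographic groups (SSA, AA/AC,
Eur, NE, EA, CSA, Ame, Lat, Oce), compiled from consortium population
summaries; `Eur` is the default and any label can be chosen per run.
Alleles with no published estimate are floored at ε = 10⁻⁶ — small enough
that they rank below every observed allele, non-zero so they remain
reportable — and \*1 is derived as 1 − Σ(others) per gene and population,
which keeps each frequency vector a proper distribution. Ties in
probability are broken deterministically by ascending numeric star order of
the pair, and within a gene exactly one candidate is flagged most probable.
Renormalised over a candidate set, the probabilities sum to 1 to within
1e-12. Genes are treated as independent; per-gene enumeration (at most
3,321 pairs) is used throughout, and the cross-gene combination space —
above 15 billion for this panel — is only ever *counted*
(`combinationSpaceSize()`), never enumerated.

## Phenotype assignment

CYP2D6 uses activity-score binning: each allele carries an activity value on
the {0, 0.5, 1} grid (no-function, decreased, normal; this package rounds
consortium quarter-values to that grid, a deliberately coarser resolution
recorded in the bundled, versioned bin table), the diplotype score is the
sum, and the bins are data (`cyp2d6_activity_bins.tsv`, tag `cpic-2023`):
0 → Poor, 0.25–1 → Intermediate, 1.25–2.25 → Normal, >2.25 → Ultrarapid.
With no increased-function CYP2D6 allele on the panel, scores above 2.25
are unreachable — correctly so, since ultrarapid CYP2D6 status arises from
gene duplications the panel cannot see.

All other genes map the unordered pair of *function classes* (normal,
decreased, no_function, increased) through a bundled lookup
(`diplotype_classes.tsv`); any allele of unknown function makes the
diplotype `Indeterminate`, so the five metabolizer classes plus
Indeterminate are the complete output alphabet. Rapid/Ultrarapid can only
arise for genes with an increased-function allele (CYP2C19's \*17, CYP2B6's
\*22). CYP3A5 is deliberately reported on the same five-class metabolizer
scale as the other genes, with the expressor/non-expressor reading
(\*1 carriers express the enzyme) left to report text: the class scale is
the one convention that is uniform across the panel, and the bundled tables
make the alternative trivial to swap in.

The function and activity assignments live in editable TSVs with provenance
comments, not in code; alleles whose clinical function the consortia have
not established are recorded `unknown` rather than guessed, which is why
rare-allele candidates often phenotype as Indeterminate.

## Drugs, guidelines, and phenoconversion

The bundled drug table holds 47 drugs (46 neuropsychiatric plus
clopidogrel) with two gene sets each: *actionable* genes, whose genotype
carries a dosing recommendation, and metabolism-associated genes kept as
metadata (several lie outside the panel). A per-drug(-gene) status table
flags CPIC and DPWG coverage, plus FDA and EMA/AIFA label metadata that
take no part in logic. Recommendation output is status plus a templated
note naming the guideline and phenotype — verbatim guideline prose is
licensed, evolving content and is out of scope. The report partitions the
evaluated drugs into actionable vs no-recommendation panels; the two sets
are disjoint and jointly exhaustive by construction.

The drug-interaction ("phenoconversion") adjustment is a data-driven rule
engine: a rule (drug, gene, shift) moves the effective phenotype along
PM < IM < NM < RM < UM by `shift` steps, clamped at the ends, flagged
`converted`, whenever the drug appears among co-medications. The shipped
rule table is **empty by design** — the default behaviour is the identity —
because inventing interaction pharmacology in code would be worse than
requiring users to supply a curated table.

## The synthetic cohort generator

`simulateCohort()` draws, per sample and gene, two alleles independently
from the chosen population's frequency distribution (Hardy–Weinberg),
renders the implied genotype at every panel SNP from the pair's signatures,
and masks each SNP independently with probability 1 − call rate. The
default call rate of 0.941 mirrors the panel's published 100-sample
validation average; the ancillary CYP3A5 SNP renders homozygous-reference.
The generator writes the same 4-column tables users supply, so simulated
data exercise the real parser and engine paths, and it returns the true
diplotypes for scoring: `recoveryRate()` reports per-gene top-1 recovery
and truth containment.

What the simulator does **not** emulate: genotyping *errors* (the default
models no-calls only; an optional per-SNP miscall probability exists for
robustness studies but defaults to 0), linkage between genes, copy-number
events, and population substructure. Passing simulation-based tests
therefore demonstrates the engine's correctness under its own model —
truth containment at any call rate, exact recovery of singleton candidate
sets, frequency-faithful sampling (chi-square goodness-of-fit at n = 5000)
— not robustness to assay artefacts.

## Numerical and interface choices

* **Canonical forms.** Genotypes are uppercased and stored as unordered
  pairs ("G/A" ≡ "A/G"; "-" sorts before bases, so "A/-" → (-, A));
  phase is never inferred from input order. Multi-base calls (`CTT/CTT`)
  and deletion codes (`-/-`, `A/-`) are first-class.
* **Validation at the edge.** Observed bases are checked against each SNP's
  reference/alternate set (plus "-"); anything else is an error naming the
  rsID, because silently accepting a stray base would corrupt the
  enumeration downstream. Unknown rsIDs are skipped with a warning; absent
  SNPs and whole missing genes are simply unconstrained.
* **Dialects.** Comma- and tab-delimited input are sniffed from extension,
  then content. Spreadsheet files are not read directly — export to
  CSV/TSV first; the format is otherwise identical.
* **Determinism.** Panel loading, enumeration, ranking (including
  tie-breaks), reports, and the simulator under a fixed seed are fully
  deterministic; report files are byte-identical across reruns.
* **Scale.** Per-gene pair signatures are precomputed once per panel load,
  making per-sample enumeration a handful of vector comparisons. The test
  suite runs the enumeration engine against an independent brute-force
  oracle on 1,000 random genotypes per gene, and the simulation checks use
  cohorts of 200–500 samples across three call-rate regimes — sizes chosen
  to give the properties real coverage while keeping a full test run in a
  few minutes on one CPU.

## Known limitations

* Calling resolution is bounded by the panel: sub-alleles sharing a
  signature are not distinguished, CYP2D6 copy number is invisible, and an
  allele defined partly by off-panel variants is recognised only through
  its on-panel tags.
* Frequencies for rare alleles are floored, not estimated; ranking among
  rare candidates within ε of each other is effectively the deterministic
  star-order tie-break.
* Phenotype tables encode current consortium consensus; they are data and
  will drift with nomenclature updates. The CYP2D6 activity grid is
  deliberately coarse ({0, 0.5, 1}).
* Guideline output is applicability status, not dosing text.
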