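Package: cypstar
Title: Star-Allele Diplotype Calling and Drug-Guideline Annotation for a
    39-SNP CYP Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers CYP star-allele diplotypes from unphased SNP genotypes on
    a 39-SNP, 5-gene pharmacogenetic panel (CYP2B6, CYP2C19, CYP2C9, CYP2D6,
    CYP3A5). Enumerates all catalogued diplotypes consistent with a sample's
    (possibly incomplete) genotype table, ranks them by Hardy-Weinberg
    population frequency, assigns metabolizer phenotypes via activity scores
    and function-class lookups, and reports CPIC/DPWG dosing-guideline
    applicability for a bundled neuropsychiatric drug list. Includes
    genotyping call-rate QC, a truth-known cohort simulator, and an
    end-to-end reporting pipeline with TSV and JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
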