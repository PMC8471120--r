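# Shared fixtures: the bundled panel is loaded once per test run.
testPanel <- loadPanel()

# Build a SampleGenotypes from (rsID, genotype) pairs through the real parser.
makeSample <- function(panel, gene, rsids, genotypes, sample = "T1") {
  tab <- data.frame(Sample = sample, Gene = gene, rsID = rsids,
                    Genotype = genotypes, stringsAsFactors = FALSE)
  parseGenotypeTable(tab, panel)[[1L]]
}

# Homozygous-reference genotype rows for a gene (one row per distinct rsID).
homRefRows <- function(panel, gene, sample = "T1") {
  snps <- panelSNPs(panel, gene)
  snps <- snps[!duplicated(snps$rsid), , drop = FALSE]
  data.frame(Sample = sample, Gene = gene, rsID = snps$rsid,
             Genotype = paste0(snps$ref_base, "/", snps$ref_base),
             stringsAsFactors = FALSE)
}

# Random per-SNP genotype table for one gene: each SNP independently missing,
# hom-ref, het or hom-alt (alts drawn from the panel's alt bases). Not
# necessarily consistent with any catalogued diplotype, so no-call paths are
# exercised too.
randomGenotypeRows <- function(panel, gene, sample = "T1",
                               pMissing = 0.15, pHet = 0.25, pHomAlt = 0.10) {
  snps <- panelSNPs(panel, gene)
  rsids <- unique(snps$rsid)
  geno <- character(length(rsids))
  for (i in seq_along(rsids)) {
    rows <- snps[snps$rsid == rsids[i], , drop = FALSE]
    ref <- rows$ref_base[1L]
    alt <- sample(rows$alt_base, 1L)
    u <- runif(1)
    geno[i] <- if (u < pMissing) ""
      else if (u < pMissing + pHet) paste0(ref, "/", alt)
      else if (u < pMissing + pHet + pHomAlt) paste0(alt, "/", alt)
      else paste0(ref, "/", ref)
  }
  data.frame(Sample = sample, Gene = gene, rsID = rsids, Genotype = geno,
             stringsAsFactors = FALSE)
}
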