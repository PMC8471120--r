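test_that("pairwise consistency follows the contributed-base definition", {
  p <- testPanel
  sg <- makeSample(p, "CYP2C19", "rs4244285", "G/A")
  expect_true(haplotypePairConsistent("*1", "*2", sg, "CYP2C19", p))
  expect_true(haplotypePairConsistent("*2", "*1", sg, "CYP2C19", p))
  expect_false(haplotypePairConsistent("*2", "*2", sg, "CYP2C19", p))
  expect_false(haplotypePairConsistent("*1", "*1", sg, "CYP2C19", p))

  # with nothing observed, every pair is consistent
  sgEmpty <- makeSample(p, "CYP2C19", "rs4244285", "")
  expect_true(haplotypePairConsistent("*3", "*8", sgEmpty, "CYP2C19", p))
})

test_that("two het variants on different SNPs force the trans diplotype", {
  p <- testPanel
  rows <- homRefRows(p, "CYP2C19")
  rows$Genotype[rows$rsID == "rs4244285"] <- "G/A"
  rows$Genotype[rows$rsID == "rs12248560"] <- "C/T"
  sg <- parseGenotypeTable(rows, p)[[1L]]
  gd <- enumerateDiplotypes(sg, "CYP2C19", p)
  expect_identical(candidates(gd)$diplotype, "*2/*17")
  expect_identical(callStatus(gd), "called")
})

test_that("hom-ref genotypes call *1/*1 uniquely; fully missing is unconstrained", {
  p <- testPanel
  sg <- parseGenotypeTable(homRefRows(p, "CYP2C19"), p)[[1L]]
  gd <- enumerateDiplotypes(sg, "CYP2C19", p)
  expect_identical(candidates(gd)$diplotype, "*1/*1")
  expect_identical(mostProbable(gd), "*1/*1")

  rows <- homRefRows(p, "CYP2C19")
  rows$Genotype <- ""
  sgM <- parseGenotypeTable(rows, p)[[1L]]
  gdM <- enumerateDiplotypes(sgM, "CYP2C19", p)
  expect_identical(callStatus(gdM), "unconstrained")
  expect_identical(nrow(candidates(gdM)), 66L)   # 11 * 12 / 2
})

test_that("contradictory genotypes yield no_call with diagnostics", {
  p <- testPanel
  # hom-alt at *2 and hom-alt at *17: no catalogued pair carries both
  rows <- homRefRows(p, "CYP2C19")
  rows$Genotype[rows$rsID == "rs4244285"] <- "A/A"
  rows$Genotype[rows$rsID == "rs12248560"] <- "T/T"
  sg <- parseGenotypeTable(rows, p)[[1L]]
  gd <- enumerateDiplotypes(sg, "CYP2C19", p)
  expect_identical(callStatus(gd), "no_call")
  expect_identical(nrow(candidates(gd)), 0L)
  expect_true("rs4244285" %in% gd@diagnostics)
})

test_that("Hardy-Weinberg probabilities: 2f1f2 het, f^2 hom, floored alleles tiny", {
  p <- testPanel
  f <- alleleFrequency(p, "CYP2C19", "Eur")
  expect_equal(diplotypeProbability(c("*1", "*2"), "CYP2C19", "Eur", p),
               2 * f[["*1"]] * f[["*2"]])
  expect_equal(diplotypeProbability(c("*2", "*2"), "CYP2C19", "Eur", p),
               f[["*2"]]^2)
  # *7 has no published Eur frequency -> floored
  expect_lte(diplotypeProbability(c("*1", "*7"), "CYP2C19", "Eur", p), 2 * p@epsilon)
  expect_error(alleleFrequency(p, "CYP2C19", "Mars"), "valid labels")
})

test_that("ranking is by descending probability with numeric-star tie-break", {
  p <- testPanel
  gd <- new("GeneDiplotypes", gene = "CYP2C19", sample = "T", status = "called",
            population = "Eur", diagnostics = character(0),
            candidates = data.frame(
              allele1 = c("*3", "*1", "*2"), allele2 = c("*3", "*2", "*17"),
              diplotype = c("*3/*3", "*1/*2", "*2/*17"),
              probability = c(0.02, 0.24, 0.02),
              most_probable = c(TRUE, FALSE, FALSE)))
  ranked <- rankAndFlag(gd)
  expect_identical(candidates(ranked)$diplotype, c("*1/*2", "*2/*17", "*3/*3"))
  expect_identical(mostProbable(ranked), "*1/*2")
  # equal probabilities: lower star pair first (*2/*17 before *3/*3)
  expect_identical(candidates(ranked)$diplotype[2L], "*2/*17")
})

test_that("enumeration equals the brute-force oracle on random genotypes", {
  set.seed(101)
  p <- testPanel
  nPer <- c(CYP2B6 = 40, CYP2C19 = 40, CYP2C9 = 40, CYP2D6 = 15, CYP3A5 = 40)
  for (g in panelGenes(p)) {
    ptab <- oraclePairTable(p, g)
    for (k in seq_len(nPer[[g]])) {
      sg <- parseGenotypeTable(randomGenotypeRows(p, g), p)[[1L]]
      gd <- enumerateDiplotypes(sg, g, p)
      expect_identical(sort(candidates(gd)$diplotype),
                       sort(bruteForceDiplotypes(p, g, sg, ptab)),
                       info = paste(g, k))
    }
  }
})

test_that("masking an observed SNP never shrinks the candidate set", {
  set.seed(202)
  p <- testPanel
  for (k in 1:25) {
    g <- sample(panelGenes(p), 1L)
    rows <- randomGenotypeRows(p, g)
    sg <- parseGenotypeTable(rows, p)[[1L]]
    before <- candidates(enumerateDiplotypes(sg, g, p))$diplotype
    observed <- which(nzchar(rows$Genotype))
    if (length(observed) == 0L) next
    rows$Genotype[sample(observed, 1L)] <- ""
    sg2 <- parseGenotypeTable(rows, p)[[1L]]
    after <- candidates(enumerateDiplotypes(sg2, g, p))$diplotype
    expect_true(all(before %in% after))
  }
})

test_that("results are invariant to base order within genotypes", {
  p <- testPanel
  rows <- homRefRows(p, "CYP2D6")
  rows$Genotype[rows$rsID == "rs16947"] <- "C/T"
  rows$Genotype[rows$rsID == "rs1135840"] <- "G/C"
  a <- enumerateDiplotypes(parseGenotypeTable(rows, p)[[1L]], "CYP2D6", p)
  rows$Genotype[rows$rsID == "rs16947"] <- "T/C"
  rows$Genotype[rows$rsID == "rs1135840"] <- "C/G"
  b <- enumerateDiplotypes(parseGenotypeTable(rows, p)[[1L]], "CYP2D6", p)
  expect_identical(candidates(a), candidates(b))
})

test_that("renormalised candidate probabilities sum to one", {
  p <- testPanel
  rows <- homRefRows(p, "CYP2C19")
  rows$Genotype <- ""
  gd <- enumerateDiplotypes(parseGenotypeTable(rows, p)[[1L]], "CYP2C19", p)
  pr <- candidates(gd)$probability
  expect_equal(sum(pr / sum(pr)), 1, tolerance = 1e-12)
})
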