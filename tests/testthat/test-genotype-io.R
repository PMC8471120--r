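test_that("genotype strings canonicalise: case, order, deletions, indels", {
  expect_identical(normalizeGenotypeString("t/c"), c("C", "T"))
  expect_identical(normalizeGenotypeString("A/-"), c("-", "A"))
  expect_identical(normalizeGenotypeString("-/-"), c("-", "-"))
  expect_identical(normalizeGenotypeString("CTT/CTT"), c("CTT", "CTT"))
  expect_identical(normalizeGenotypeString(" g / a "), c("A", "G"))
  expect_error(normalizeGenotypeString("GAT"), "exactly one '/'")
  expect_error(normalizeGenotypeString("A/G/T"), "exactly one '/'")
  expect_error(normalizeGenotypeString("/A"), "empty side")
})

test_that("the 4-column table parses to canonical per-sample calls", {
  p <- testPanel
  tab <- data.frame(
    Sample = c("S1", "S1", "S1"),
    Gene = c("CYP2C19", "CYP2D6", "CYP2D6"),
    rsID = c("rs4244285", "rs5030655", "rs5030656"),
    Genotype = c("G/A", "-/-", "CTT/CTT")
  )
  sg <- parseGenotypeTable(tab, p)[["S1"]]
  cl <- genotypeCalls(sg)
  expect_identical(cl$base1[cl$rsid == "rs4244285"], "A")
  expect_identical(cl$base2[cl$rsid == "rs4244285"], "G")
  expect_identical(cl$base1[cl$rsid == "rs5030655"], "-")  # hom deletion
  expect_identical(cl$base1[cl$rsid == "rs5030656"], "CTT")
  expect_false(any(cl$missing))
})

test_that("header matching is case-insensitive and dialects agree", {
  p <- testPanel
  tab <- data.frame(SAMPLE = "S1", gene = "CYP2C19",
                    RsId = "rs4244285", GENOTYPE = "g/a")
  sg <- parseGenotypeTable(tab, p)[["S1"]]
  expect_identical(genotypeCalls(sg)$base1, "A")

  rows <- homRefRows(p, "CYP2C19", sample = "D1")
  csv <- tempfile(fileext = ".csv")
  tsv <- tempfile(fileext = ".tsv")
  write.table(rows, csv, sep = ",", quote = FALSE, row.names = FALSE)
  write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- parseGenotypeTable(csv, p)[["D1"]]
  b <- parseGenotypeTable(tsv, p)[["D1"]]
  expect_identical(genotypeCalls(a), genotypeCalls(b))
})

test_that("parser errors and warnings name the offending entity", {
  p <- testPanel
  expect_error(
    parseGenotypeTable(data.frame(Sample = "S1", Gene = "CYP2C19",
                                  Genotype = "G/A"), p),
    "rsid")
  # conflicting duplicate
  tab <- data.frame(Sample = "S1", Gene = "CYP2C19",
                    rsID = c("rs4244285", "rs4244285"),
                    Genotype = c("G/A", "A/A"))
  expect_error(parseGenotypeTable(tab, p), "conflicting.*rs4244285")
  # identical duplicate is tolerated
  tab$Genotype <- c("G/A", "A/G")
  expect_silent(parseGenotypeTable(tab, p))
  # unknown rsID skipped with warning
  tab2 <- data.frame(Sample = "S1", Gene = "CYP2C19",
                     rsID = c("rs4244285", "rs999999"),
                     Genotype = c("G/A", "C/C"))
  expect_warning(res <- parseGenotypeTable(tab2, p), "rs999999")
  expect_identical(nrow(genotypeCalls(res[["S1"]])), 1L)
  # base outside the panel's ref/alt set
  tab3 <- data.frame(Sample = "S1", Gene = "CYP2C19",
                     rsID = "rs4244285", Genotype = "G/C")
  expect_error(parseGenotypeTable(tab3, p), "rs4244285")
})

test_that("empty genotypes become explicit missing calls", {
  p <- testPanel
  tab <- data.frame(Sample = "S1", Gene = "CYP2C19",
                    rsID = c("rs4244285", "rs12248560"),
                    Genotype = c("", "NA"))
  cl <- genotypeCalls(parseGenotypeTable(tab, p)[["S1"]])
  expect_true(all(cl$missing))
  expect_true(all(is.na(cl$base1)))
})

test_that("serialise-then-parse is the identity", {
  p <- testPanel
  sims <- simulateCohort(3, panel = p, seed = 5, callRate = 0.9)
  sgl <- parseGenotypeTable(cohortGenotypeTable(sims), p)
  path <- tempfile(fileext = ".tsv")
  writeGenotypeTable(sgl, path)
  sgl2 <- parseGenotypeTable(path, p)
  expect_identical(names(sgl), names(sgl2))
  for (id in names(sgl)) {
    expect_identical(genotypeCalls(sgl[[id]]), genotypeCalls(sgl2[[id]]))
  }
})

test_that("call rate follows called/total with a strict 90% pass rule", {
  p <- testPanel
  full <- homRefRows(p, "CYP2B6")
  for (g in setdiff(panelGenes(p), "CYP2B6")) full <- rbind(full, homRefRows(p, g))
  sg <- parseGenotypeTable(full, p)[[1L]]
  cr <- computeCallRate(sg, p)
  expect_identical(cr$called, 39L)
  expect_identical(cr$rate, 1)
  expect_true(cr$pass)

  mask <- function(rows, k) { rows$Genotype[seq_len(k)] <- ""; rows }
  cr37 <- computeCallRate(parseGenotypeTable(mask(full, 2), p)[[1L]], p)
  expect_equal(cr37$rate, 37 / 39)
  expect_true(cr37$pass)    # 0.949 > 0.90

  cr35 <- computeCallRate(parseGenotypeTable(mask(full, 4), p)[[1L]], p)
  expect_equal(cr35$rate, 35 / 39)
  expect_false(cr35$pass)   # 0.897 <= 0.90

  # invariant to row order and to which SNPs are missing
  shuffled <- full[rev(seq_len(nrow(full))), ]
  shuffled$Genotype[(nrow(shuffled) - 3):nrow(shuffled)] <- ""
  crS <- computeCallRate(parseGenotypeTable(shuffled, p)[[1L]], p)
  expect_equal(crS$rate, 35 / 39)
})
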