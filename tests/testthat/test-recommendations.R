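phenoFixture <- function(sample = "S1") {
  data.frame(
    sample = sample,
    gene = c("CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A5"),
    diplotype = c("*1/*1", "*2/*2", "*1/*1", "*1/*1", "*3/*3"),
    phenotype = c("Normal Metabolizer", "Poor Metabolizer",
                  "Normal Metabolizer", "Normal Metabolizer",
                  "Poor Metabolizer"),
    activity_score = c(NA, NA, NA, 2, NA),
    stringsAsFactors = FALSE
  )
}

test_that("guideline-covered drug-gene pairs are actionable, noRec drugs are not", {
  p <- testPanel
  recs <- lookupRecommendations(phenoFixture(), p,
                                drugs = c("Citalopram", "Olanzapine"),
                                guideline = "CPIC")
  cit <- recs[recs$drug == "Citalopram", ]
  expect_identical(cit$status, "actionable")
  expect_identical(cit$gene, "CYP2C19")
  expect_identical(cit$phenotype, "Poor Metabolizer")
  ola <- recs[recs$drug == "Olanzapine", ]
  expect_identical(ola$status, "no_recommendation")
})

test_that("empty phenotype lists and unknown drugs are handled explicitly", {
  p <- testPanel
  expect_identical(nrow(lookupRecommendations(phenoFixture()[0, ], p)), 0L)
  expect_error(lookupRecommendations(phenoFixture(), p, drugs = "Citaloprm"),
               "Citalopram")
})

test_that("unphenotyped actionable genes yield not_applicable, never actionable", {
  p <- testPanel
  ph <- phenoFixture()
  ph <- ph[ph$gene != "CYP2D6", ]
  recs <- lookupRecommendations(ph, p, drugs = "Fluoxetine", guideline = "CPIC")
  expect_identical(recs$status, "not_applicable")
})

test_that("drug partition is disjoint and covers every evaluated drug", {
  p <- testPanel
  recs <- lookupRecommendations(phenoFixture(), p)
  part <- partitionDrugReport(recs)
  expect_length(intersect(part$actionable, part$no_recommendation), 0L)
  expect_setequal(c(part$actionable, part$no_recommendation),
                  drugGeneMap(p)$drug)
  # all actionable genes lie on the panel, so every guideline-covered drug
  # is actionable for a fully phenotyped sample
  covered <- drugGeneMap(p)$drug[nzchar(drugGeneMap(p)$actionable_genes)]
  expect_setequal(part$actionable, covered)
})

test_that("drugs flagged noRec in both guidelines are never actionable", {
  p <- testPanel
  gl <- guidelineStatus(p)
  noRec <- gl$drug[gl$cpic == "noRec" & gl$dpwg == "noRec"]
  phenos <- list(phenoFixture(), within(phenoFixture(), {
    phenotype <- rep("Ultrarapid Metabolizer", 5)
  }))
  for (ph in phenos) {
    recs <- lookupRecommendations(ph, p)
    expect_false(any(recs$drug %in% noRec & recs$status == "actionable"))
  }
})

test_that("recommendations are a pure function of their inputs", {
  p <- testPanel
  a <- lookupRecommendations(phenoFixture(), p)
  b <- lookupRecommendations(phenoFixture(), p)
  expect_identical(a, b)
})

test_that("phenoconversion shifts are clamped, flagged, and default to identity", {
  p <- testPanel
  ph <- phenoFixture()
  # empty bundled rules: identity
  out <- applyPhenoconversion(ph, comedications = "Fluoxetine", panel = p)
  expect_identical(out$phenotype, ph$phenotype)
  expect_false(any(out$converted))

  rules <- data.frame(drug = "inhibitorX", gene = "CYP2D6", shift = -2L)
  out2 <- applyPhenoconversion(ph, "inhibitorX", rules = rules, panel = p)
  expect_identical(out2$phenotype[out2$gene == "CYP2D6"], "Poor Metabolizer")
  expect_true(out2$converted[out2$gene == "CYP2D6"])
  # absent co-medication: rule inert
  out3 <- applyPhenoconversion(ph, character(0), rules = rules, panel = p)
  expect_identical(out3$phenotype, ph$phenotype)
  # shift below PM clamps at PM
  rules$shift <- -5L
  out4 <- applyPhenoconversion(ph, "inhibitorX", rules = rules, panel = p)
  expect_identical(out4$phenotype[out4$gene == "CYP2D6"], "Poor Metabolizer")
  # unknown gene in rules is a load error
  badRules <- data.frame(drug = "x", gene = "CYP9Z9", shift = 1L)
  expect_error(applyPhenoconversion(ph, "x", rules = badRules, panel = p),
               "CYP9Z9")
})
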