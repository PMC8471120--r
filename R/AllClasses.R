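#' @import methods
NULL

#' PgxPanel: a pharmacogenetic genotyping panel with reference knowledge
#'
#' Container for a star-allele genotyping panel: the assayed SNPs, the
#' star-allele inventory per gene, per-allele population frequencies, allele
#' function classes, phenotype lookup tables and the drug--gene guideline map.
#' Build one with [loadPanel()]; do not call `new()` directly.
#'
#' @slot snps data.frame of assayed variants, one row per (rsID, alt base):
#'   columns `gene`, `rsid`, `ref_base`, `alt_base`, `tagged_alleles`
#'   (comma-separated star alleles), `assay_id`, `variant_label`, `ancillary`.
#'   Ancillary rows are assayed and QC-counted but excluded from allele
#'   signatures (they tag sub-alleles below panel resolution).
#' @slot alleles data.frame: `gene`, `allele`, `callable`.
#' @slot frequencies data.frame (long): `gene`, `allele`, `population`,
#'   `frequency`. Complete over callable alleles x populations; unpublished
#'   frequencies are floored at `epsilon` and `*1` is derived by subtraction.
#' @slot functions data.frame: `gene`, `allele`, `function_class`,
#'   `activity_value`.
#' @slot diplotypeClasses data.frame mapping unordered function-class pairs to
#'   metabolizer phenotypes (used for all genes except CYP2D6).
#' @slot activityBins data.frame of CYP2D6 activity-score bins.
#' @slot drugs data.frame: `drug`, `actionable_genes`, `metabolism_genes`
#'   (semicolon-separated).
#' @slot guidelines data.frame of per-drug(-gene) CPIC/DPWG status and label
#'   metadata.
#' @slot phenoconversionRules data.frame: `drug`, `gene`, `shift` (empty by
#'   default).
#' @slot populations character vector of population labels.
#' @slot epsilon numeric floor used for unpublished allele frequencies.
#' @slot cache internal per-gene lookup structures (definition matrices,
#'   haplotype base matrices, precomputed diplotype genotype keys).
#'
#' @seealso [loadPanel()], [validatePanel()], [panelSNPs()], [starAlleles()]
#' @export
setClass("PgxPanel",
  representation(
    snps = "data.frame",
    alleles = "data.frame",
    frequencies = "data.frame",
    functions = "data.frame",
    diplotypeClasses = "data.frame",
    activityBins = "data.frame",
    drugs = "data.frame",
    guidelines = "data.frame",
    phenoconversionRules = "data.frame",
    populations = "character",
    epsilon = "numeric",
    cache = "list"
  )
)

setValidity("PgxPanel", function(object) {
  msg <- validatePanel(object)
  if (length(msg) == 0L) TRUE else msg
})

#' SampleGenotypes: one sample's observed genotypes at panel SNPs
#'
#' Unordered per-SNP base pairs for one sample, in canonical form (uppercase,
#' lexicographic order with "-" sorting first). Rows are only the SNPs present
#' in the input; panel SNPs absent from the input are treated as missing
#' (unconstrained) downstream.
#'
#' @slot sample sample identifier.
#' @slot calls data.frame with columns `gene`, `rsid`, `base1`, `base2`,
#'   `missing`. For missing calls `base1`/`base2` are `NA`.
#'
#' @seealso [parseGenotypeTable()], [computeCallRate()], [enumerateDiplotypes()]
#' @export
setClass("SampleGenotypes",
  representation(sample = "character", calls = "data.frame")
)

setValidity("SampleGenotypes", function(object) {
  msg <- character()
  cl <- object@calls
  need <- c("gene", "rsid", "base1", "base2", "missing")
  if (!all(need %in% names(cl))) {
    msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(cl$rsid)) {
      msg <- c(msg, paste("duplicated rsID in calls:",
                          paste(unique(cl$rsid[duplicated(cl$rsid)]), collapse = ", ")))
    }
    ok <- cl$missing | (!is.na(cl$base1) & !is.na(cl$base2))
    if (!all(ok)) msg <- c(msg, "non-missing calls must carry two bases")
  }
  if (length(object@sample) != 1L) msg <- c(msg, "sample must be a single identifier")
  if (length(msg) == 0L) TRUE else msg
})

#' GeneDiplotypes: candidate star-allele diplotypes for one sample and gene
#'
#' The result of [enumerateDiplotypes()]: every unordered pair of callable
#' star alleles consistent with the sample's observed genotypes, with
#' Hardy--Weinberg probabilities in the chosen population, sorted by
#' descending probability, the top candidate flagged `most_probable`.
#'
#' @slot gene gene symbol.
#' @slot sample sample identifier.
#' @slot candidates data.frame: `allele1`, `allele2`, `diplotype`,
#'   `probability`, `most_probable`.
#' @slot status one of `"called"` (constrained, >= 1 candidate),
#'   `"unconstrained"` (no genotype observed for the gene; all pairs remain),
#'   `"no_call"` (observed genotypes match no catalogued pair).
#' @slot population population label used for the probabilities.
#' @slot diagnostics for `no_call`, the rsIDs that constrained the search.
#'
#' @export
setClass("GeneDiplotypes",
  representation(
    gene = "character",
    sample = "character",
    candidates = "data.frame",
    status = "character",
    population = "character",
    diagnostics = "character"
  )
)

setValidity("GeneDiplotypes", function(object) {
  msg <- character()
  if (!object@status %in% c("called", "unconstrained", "no_call")) {
    msg <- c(msg, "status must be called/unconstrained/no_call")
  }
  if (object@status == "no_call" && nrow(object@candidates) > 0L) {
    msg <- c(msg, "no_call implies an empty candidate set")
  }
  if (object@status != "no_call" && nrow(object@candidates) > 0L &&
      sum(object@candidates$most_probable) != 1L) {
    msg <- c(msg, "exactly one candidate must be flagged most_probable")
  }
  if (length(msg) == 0L) TRUE else msg
})
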