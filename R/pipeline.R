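#' Run the full calling pipeline on a genotype table
#'
#' End-to-end driver: parse the 4-column genotype table, QC call rates,
#' enumerate and rank diplotypes per gene, assign metabolizer phenotypes,
#' and annotate drug guideline applicability. One report per sample; pooled
#' multi-sample files and files with missing SNPs or whole genes are
#' supported (missing genes are reported as unconstrained, not dropped).
#'
#' Written outputs (all under `outputDir`): `genotypes.tsv` (input echo),
#' `call_rates.tsv`, `diplotypes.tsv` (all candidates), `phenotypes.tsv`
#' (most-probable diplotype per gene), `rare_diplotypes.tsv` (non-top
#' candidates with phenotypes and probabilities), `recommendations.tsv`,
#' and `report.json` (the canonical machine-readable report). Outputs are a
#' pure function of inputs and options, hence byte-identical across reruns.
#'
#' @param input path to a genotype table (CSV/TSV) or a data.frame.
#' @param outputDir directory for report files (created if absent); `NULL`
#'   skips writing and only returns the reports.
#' @param panel a [PgxPanel-class] object (default: the bundled panel).
#' @param population population label for frequency ranking.
#' @param guideline `"both"`, `"CPIC"` or `"DPWG"`.
#' @param callRateThreshold QC pass threshold (default 0.90).
#' @param comedications optional character vector of co-medications applied
#'   to every sample via [applyPhenoconversion()].
#' @param phenoconversionRules optional rules data.frame (default: the
#'   panel's bundled table, which is empty).
#' @return Invisibly, a named list of per-sample reports; each report holds
#'   `sample`, `genotypes`, `call_rate`, `diplotypes`, `phenotypes`,
#'   `rare_diplotypes`, `recommendations`, `drug_partition`.
#' @examples
#' panel <- loadPanel()
#' sims <- simulateCohort(1, panel = panel, seed = 11, callRate = 1)
#' rep <- runPipeline(sims[[1]]$rows, outputDir = NULL, panel = panel)
#' rep[[1]]$phenotypes
#' @export
runPipeline <- function(input, outputDir = NULL, panel = loadPanel(),
                        population = "Eur",
                        guideline = c("both", "CPIC", "DPWG"),
                        callRateThreshold = 0.90,
                        comedications = character(0),
                        phenoconversionRules = NULL) {
  guideline <- match.arg(guideline)
  sgList <- parseGenotypeTable(input, panel)
  if (length(sgList) == 0L) stop("no samples found in input", call. = FALSE)

  qc <- callRateTable(sgList, panel, callRateThreshold)
  calls <- callDiplotypes(sgList, panel, population)

  reports <- list()
  for (sg in sgList) {
    id <- sg@sample
    sampleCalls <- calls[calls$sample == id, , drop = FALSE]
    phenos <- phenotypeTable(sampleCalls, panel)
    phenos <- applyPhenoconversion(phenos, comedications,
                                   rules = phenoconversionRules, panel = panel)
    allPhenos <- phenotypeTable(sampleCalls, panel, all = TRUE)
    rare <- allPhenos[!paste(allPhenos$gene, allPhenos$diplotype) %in%
                        paste(phenos$gene, phenos$diplotype), , drop = FALSE]
    rownames(rare) <- NULL
    recs <- lookupRecommendations(phenos, panel, guideline = guideline)
    reports[[id]] <- list(
      sample = id,
      genotypes = writeGenotypeTable(sg),
      call_rate = qc[qc$sample == id, , drop = FALSE],
      diplotypes = sampleCalls,
      phenotypes = phenos,
      rare_diplotypes = rare,
      recommendations = recs,
      drug_partition = partitionDrugReport(recs)
    )
  }

  if (!is.null(outputDir)) {
    writeReports(reports, outputDir, panel, population, guideline)
  }
  invisible(reports)
}

writeReports <- function(reports, outputDir, panel, population, guideline) {
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outputDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  stack <- function(field) {
    out <- do.call(rbind, lapply(reports, `[[`, field))
    rownames(out) <- NULL
    out
  }
  wt(stack("genotypes"), "genotypes.tsv")
  wt(stack("call_rate"), "call_rates.tsv")
  wt(stack("diplotypes"), "diplotypes.tsv")
  wt(stack("phenotypes"), "phenotypes.tsv")
  wt(stack("rare_diplotypes"), "rare_diplotypes.tsv")
  wt(stack("recommendations"), "recommendations.tsv")

  json <- list(
    metadata = list(
      tool = "cypstar",
      version = as.character(utils::packageVersion("cypstar")),
      population = population,
      guideline = guideline,
      genes = panelGenes(panel)
    ),
    samples = unname(reports)
  )
  jsonlite::write_json(json, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(NULL)
}
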