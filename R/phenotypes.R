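#' Function class and activity value of a star allele
#'
#' Looks up the bundled allele-function table (consortium-derived). Alleles
#' whose clinical function has not been established return
#' `function_class = "unknown"` with `NA` activity.
#'
#' @param gene gene symbol.
#' @param allele star-allele name (must be inventoried for `gene`).
#' @param panel a [PgxPanel-class] object.
#' @return List with elements `function_class` and `activity_value`.
#' @examples
#' panel <- loadPanel()
#' alleleFunction("CYP2C19", "*2", panel)   # no_function
#' alleleFunction("CYP2C19", "*17", panel)  # increased
#' @export
alleleFunction <- function(gene, allele, panel) {
  assertPanelGene(panel, gene)
  fn <- panel@functions
  i <- which(fn$gene == gene & fn$allele == allele)
  if (length(i) == 0L) {
    stop("allele ", allele, " is not inventoried for ", gene, call. = FALSE)
  }
  list(function_class = fn$function_class[i[1L]],
       activity_value = fn$activity_value[i[1L]])
}

#' Metabolizer phenotype of a diplotype
#'
#' Maps an unordered star-allele pair to a metabolizer phenotype. CYP2D6 is
#' binned by activity score (the sum of the two alleles' activity values,
#' against the bundled bin table); all other genes use the bundled lookup
#' keyed by the unordered pair of function classes. Any allele of unknown
#' function yields `Indeterminate`. The mapping is symmetric in the pair.
#'
#' @param gene gene symbol.
#' @param pair character vector of two star-allele names.
#' @param panel a [PgxPanel-class] object.
#' @return One-row data.frame: `gene`, `diplotype`, `phenotype`,
#'   `activity_score` (NA where the gene is not score-binned).
#' @examples
#' panel <- loadPanel()
#' callPhenotype("CYP2C19", c("*2", "*2"), panel)   # Poor Metabolizer
#' callPhenotype("CYP2D6", c("*1", "*1"), panel)    # Normal Metabolizer, score 2
#' @export
callPhenotype <- function(gene, pair, panel) {
  stopifnot(length(pair) == 2L)
  f1 <- alleleFunction(gene, pair[1L], panel)
  f2 <- alleleFunction(gene, pair[2L], panel)
  label <- diplotypeLabel(pair[1L], pair[2L])

  if (f1$function_class == "unknown" || f2$function_class == "unknown") {
    return(phenotypeRow(gene, label, "Indeterminate", NA_real_))
  }

  if (gene == "CYP2D6") {
    score <- f1$activity_value + f2$activity_value
    if (is.na(score)) {
      return(phenotypeRow(gene, label, "Indeterminate", NA_real_))
    }
    bins <- panel@activityBins
    hit <- which(bins$lower <= score & score <= bins$upper)
    pheno <- if (length(hit) > 0L) bins$phenotype[hit[1L]] else "Indeterminate"
    return(phenotypeRow(gene, label, pheno, score))
  }

  cls <- panel@diplotypeClasses
  hit <- which((cls$function_1 == f1$function_class & cls$function_2 == f2$function_class) |
               (cls$function_1 == f2$function_class & cls$function_2 == f1$function_class))
  pheno <- if (length(hit) > 0L) cls$phenotype[hit[1L]] else "Indeterminate"
  phenotypeRow(gene, label, pheno, NA_real_)
}

phenotypeRow <- function(gene, diplotype, phenotype, score) {
  data.frame(gene = gene, diplotype = diplotype, phenotype = phenotype,
             activity_score = score, stringsAsFactors = FALSE)
}

#' Phenotype table for a cohort's diplotype calls
#'
#' Attaches metabolizer phenotypes to diplotype calls (as produced by
#' [callDiplotypes()]). By default only the most-probable diplotype per
#' sample and gene is phenotyped; with `all = TRUE` every candidate is
#' (the "possible rare diplotypes" view).
#'
#' @param calls data.frame from [callDiplotypes()].
#' @param panel a [PgxPanel-class] object.
#' @param all phenotype every candidate instead of the top one.
#' @return data.frame: `sample`, `gene`, `diplotype`, `phenotype`,
#'   `activity_score` (plus `probability` when `all = TRUE`).
#' @export
phenotypeTable <- function(calls, panel, all = FALSE) {
  rows <- if (all) calls[!is.na(calls$diplotype), , drop = FALSE]
          else calls[calls$most_probable, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    ph <- callPhenotype(rows$gene[i], c(rows$allele1[i], rows$allele2[i]), panel)
    rec <- data.frame(sample = rows$sample[i], ph, stringsAsFactors = FALSE)
    if (all) rec$probability <- rows$probability[i]
    out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0L) {
    res <- data.frame(sample = character(), gene = character(),
                      diplotype = character(), phenotype = character(),
                      activity_score = numeric(), stringsAsFactors = FALSE)
    if (all) res$probability <- numeric()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
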