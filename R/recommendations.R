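#' Guideline recommendation status per drug and gene
#'
#' Joins one sample's per-gene metabolizer phenotypes to the bundled drug
#' table and guideline-status flags. For each drug, each actionable gene that
#' was phenotyped yields one record per requested guideline: `actionable` if
#' that guideline has a recommendation for the drug--gene pair,
#' `no_recommendation` otherwise. Actionable genes without a phenotype yield
#' `not_applicable` records; drugs with no actionable gene yield one
#' `no_recommendation` record. Verbatim guideline prose is out of scope: the
#' `note` is a template citing the guideline and phenotype.
#'
#' @param phenotypes data.frame as from [phenotypeTable()] (one sample).
#' @param panel a [PgxPanel-class] object.
#' @param drugs optional subset of drug names (default: all bundled drugs).
#'   Unknown names are an error listing nearest matches.
#' @param guideline `"CPIC"`, `"DPWG"`, or `"both"`.
#' @return data.frame: `sample`, `drug`, `gene`, `phenotype`, `guideline`,
#'   `status`, `note`, ordered by (drug, gene, guideline).
#' @examples
#' panel <- loadPanel()
#' ph <- data.frame(sample = "S1", gene = "CYP2C19", diplotype = "*2/*2",
#'                  phenotype = "Poor Metabolizer", activity_score = NA)
#' recs <- lookupRecommendations(ph, panel, drugs = "Citalopram")
#' recs$status
#' @export
lookupRecommendations <- function(phenotypes, panel, drugs = NULL,
                                  guideline = c("both", "CPIC", "DPWG")) {
  guideline <- match.arg(guideline)
  guides <- if (guideline == "both") c("CPIC", "DPWG") else guideline
  dmap <- panel@drugs
  if (is.null(drugs)) {
    drugs <- dmap$drug
  } else {
    unknown <- setdiff(drugs, dmap$drug)
    if (length(unknown) > 0L) {
      near <- unlist(lapply(unknown, function(d) {
        dmap$drug[agrepl(d, dmap$drug, ignore.case = TRUE, max.distance = 0.3)]
      }))
      stop("unknown drug name(s): ", paste(unknown, collapse = ", "),
           if (length(near) > 0L) paste0("; did you mean: ",
                                         paste(unique(near), collapse = ", "), "?"),
           call. = FALSE)
    }
  }
  if (nrow(phenotypes) == 0L) {
    return(emptyRecommendations())
  }
  sample <- unique(phenotypes$sample)
  if (length(sample) != 1L) {
    stop("lookupRecommendations expects phenotypes of a single sample",
         call. = FALSE)
  }

  out <- list()
  for (d in sort(drugs)) {
    row <- dmap[dmap$drug == d, , drop = FALSE]
    actionable <- splitGenes(row$actionable_genes)
    if (length(actionable) == 0L) {
      out[[length(out) + 1L]] <- recRow(sample, d, NA_character_, NA_character_,
        paste(guides, collapse = "+"), "no_recommendation",
        "No dosing recommendation reported in the guideline for this drug.")
      next
    }
    for (g in sort(actionable)) {
      ph <- phenotypes$phenotype[phenotypes$gene == g]
      for (gl in guides) {
        st <- guidelineFlag(panel, d, g, gl)
        if (length(ph) == 0L) {
          out[[length(out) + 1L]] <- recRow(sample, d, g, NA_character_, gl,
            "not_applicable", paste0(g, " was not phenotyped for this sample."))
        } else if (st == "has_recommendation") {
          out[[length(out) + 1L]] <- recRow(sample, d, g, ph[1L], gl, "actionable",
            paste0(gl, " publishes a dosing recommendation for ", d, " in ",
                   g, " ", ph[1L], " carriers; consult the ", gl, " guideline."))
        } else {
          out[[length(out) + 1L]] <- recRow(sample, d, g, ph[1L], gl,
            "no_recommendation",
            paste0("No ", gl, " recommendation reported for ", d, " / ", g, "."))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

recRow <- function(sample, drug, gene, phenotype, guideline, status, note) {
  data.frame(sample = sample, drug = drug, gene = gene, phenotype = phenotype,
             guideline = guideline, status = status, note = note,
             stringsAsFactors = FALSE)
}

emptyRecommendations <- function() {
  data.frame(sample = character(), drug = character(), gene = character(),
             phenotype = character(), guideline = character(),
             status = character(), note = character(), stringsAsFactors = FALSE)
}

splitGenes <- function(x) {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1L]]
}

guidelineFlag <- function(panel, drug, gene, guideline) {
  g <- panel@guidelines
  col <- tolower(guideline)
  i <- which(g$drug == drug & g$gene == gene)
  if (length(i) == 0L) i <- which(g$drug == drug & !nzchar(g$gene))
  if (length(i) == 0L) return("noRec")
  g[[col]][i[1L]]
}

#' Partition a sample's drug list into actionable vs no-recommendation sets
#'
#' Reduces a recommendation table to the two report panels: drugs with at
#' least one `actionable` record, and all remaining evaluated drugs. The two
#' sets are disjoint and their union is the evaluated drug list.
#'
#' @param recs data.frame from [lookupRecommendations()] (one sample).
#' @return List with character vectors `actionable` and `no_recommendation`.
#' @export
partitionDrugReport <- function(recs) {
  drugs <- sort(unique(recs$drug))
  act <- sort(unique(recs$drug[recs$status == "actionable"]))
  list(actionable = act, no_recommendation = setdiff(drugs, act))
}

#' Adjust effective phenotypes for drug--drug interactions (phenoconversion)
#'
#' Applies a data-driven rule table: each rule `(drug, gene, shift)` moves the
#' effective metabolizer phenotype of `gene` by `shift` steps on the ordered
#' scale PM < IM < NM < RM < UM (clamped at the ends) whenever `drug` appears
#' among the sample's co-medications. Adjusted rows are flagged `converted`.
#' Indeterminate phenotypes are never shifted. With an empty rule table
#' (the shipped default) the function is the identity apart from adding the
#' bookkeeping columns.
#'
#' @param phenotypes data.frame as from [phenotypeTable()].
#' @param comedications character vector of co-medication drug names.
#' @param rules data.frame with columns `drug`, `gene`, `shift`; defaults to
#'   the panel's bundled (empty) table when `panel` is given.
#' @param panel optional [PgxPanel-class]; used for the default rules and to
#'   check rule genes.
#' @return `phenotypes` with `phenotype` possibly shifted and an added logical
#'   `converted` column.
#' @export
applyPhenoconversion <- function(phenotypes, comedications = character(0),
                                 rules = NULL, panel = NULL) {
  if (is.null(rules)) {
    if (is.null(panel)) stop("supply either rules or a panel", call. = FALSE)
    rules <- panel@phenoconversionRules
  }
  need <- c("drug", "gene", "shift")
  if (!all(need %in% names(rules))) {
    stop("rules table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(panel) && nrow(rules) > 0L) {
    bad <- setdiff(unique(rules$gene), panelGenes(panel))
    if (length(bad) > 0L) {
      stop("phenoconversion rule references unknown gene(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  scale <- c("Poor Metabolizer", "Intermediate Metabolizer",
             "Normal Metabolizer", "Rapid Metabolizer", "Ultrarapid Metabolizer")
  out <- phenotypes
  out$converted <- FALSE
  active <- rules[rules$drug %in% comedications, , drop = FALSE]
  for (i in seq_len(nrow(active))) {
    hit <- which(out$gene == active$gene[i] & out$phenotype %in% scale)
    for (j in hit) {
      pos <- match(out$phenotype[j], scale) + active$shift[i]
      pos <- min(max(pos, 1L), length(scale))
      if (scale[pos] != out$phenotype[j]) {
        out$phenotype[j] <- scale[pos]
        out$converted[j] <- TRUE
      }
    }
  }
  out
}
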