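#' Is a star-allele pair consistent with a sample's observed genotypes?
#'
#' A pair (a1, a2) is consistent when, at every non-missing observed panel SNP
#' of the gene, the unordered pair of bases the two haplotypes contribute
#' equals the observed base pair. An allele contributes its defining alt base
#' at SNPs in its definition and the reference base everywhere else
#' (closed-world exact matching at panel resolution). Missing SNPs impose no
#' constraint, so removing observations can only widen the consistent set.
#'
#' @param a1,a2 star-allele names (callable alleles of `gene`).
#' @param sg a [SampleGenotypes-class] object.
#' @param gene gene symbol.
#' @param panel a [PgxPanel-class] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' panel <- loadPanel()
#' tab <- data.frame(Sample = "S1", Gene = "CYP2C19",
#'                   rsID = "rs4244285", Genotype = "G/A")
#' sg <- parseGenotypeTable(tab, panel)[[1]]
#' haplotypePairConsistent("*1", "*2", sg, "CYP2C19", panel)  # TRUE
#' haplotypePairConsistent("*2", "*2", sg, "CYP2C19", panel)  # FALSE
#' @export
haplotypePairConsistent <- function(a1, a2, sg, gene, panel) {
  cc <- geneCache(panel, gene)
  if (!a1 %in% cc$alleles || !a2 %in% cc$alleles) {
    stop("allele(s) not callable for ", gene, ": ",
         paste(setdiff(c(a1, a2), cc$alleles), collapse = ", "), call. = FALSE)
  }
  obs <- observedGenotypeKeys(sg, cc)
  if (length(obs) == 0L) return(TRUE)
  for (s in names(obs)) {
    if (genotypeKey(cc$base[a1, s], cc$base[a2, s]) != obs[[s]]) return(FALSE)
  }
  TRUE
}

# Observed (non-missing) genotype keys for the gene's constraint SNPs,
# named by rsID. Ancillary SNPs never constrain.
observedGenotypeKeys <- function(sg, cc) {
  cl <- sg@calls
  cl <- cl[!cl$missing & cl$rsid %in% cc$snps, , drop = FALSE]
  if (nrow(cl) == 0L) return(stats::setNames(character(0), character(0)))
  stats::setNames(paste0(cl$base1, "/", cl$base2), cl$rsid)
}

#' Enumerate all star-allele diplotypes consistent with a sample's genotypes
#'
#' Scans every unordered pair (with replacement) of the gene's callable star
#' alleles, keeps the pairs consistent with the observed genotypes (see
#' [haplotypePairConsistent()]), attaches Hardy--Weinberg probabilities in the
#' chosen population, and ranks them (see [rankAndFlag()]). The result is
#' independent of input row order and of the base order within each genotype.
#'
#' Status is `"unconstrained"` when no genotype is observed for the gene (all
#' pairs remain possible), `"no_call"` when the observations match no
#' catalogued pair (the constraining rsIDs are reported as diagnostics), and
#' `"called"` otherwise.
#'
#' @param sg a [SampleGenotypes-class] object.
#' @param gene gene symbol.
#' @param panel a [PgxPanel-class] object.
#' @param population population label used for ranking (default `"Eur"`).
#' @return A [GeneDiplotypes-class] object.
#' @examples
#' panel <- loadPanel()
#' tab <- data.frame(Sample = "S1", Gene = "CYP2C19",
#'                   rsID = c("rs4244285", "rs12248560"),
#'                   Genotype = c("G/A", "C/T"))
#' sg <- parseGenotypeTable(tab, panel)[[1]]
#' enumerateDiplotypes(sg, "CYP2C19", panel)
#' @export
enumerateDiplotypes <- function(sg, gene, panel, population = "Eur") {
  cc <- geneCache(panel, gene)
  freqs <- alleleFrequency(panel, gene, population)
  obs <- observedGenotypeKeys(sg, cc)

  keep <- rep(TRUE, length(cc$pair1))
  for (s in names(obs)) keep <- keep & (cc$keys[, s] == obs[[s]])

  status <- if (length(obs) == 0L) "unconstrained"
            else if (!any(keep)) "no_call"
            else "called"

  idx <- which(keep)
  cand <- data.frame(
    allele1 = cc$pair1[idx], allele2 = cc$pair2[idx],
    diplotype = if (length(idx) > 0L) paste0(cc$pair1[idx], "/", cc$pair2[idx])
                else character(0),
    probability = diplotypeProbabilityVec(cc$pair1[idx], cc$pair2[idx], freqs),
    most_probable = rep(FALSE, length(idx)),
    stringsAsFactors = FALSE
  )

  new("GeneDiplotypes",
    gene = gene, sample = sg@sample, candidates = rankCandidates(cand),
    status = status, population = population,
    diagnostics = if (status == "no_call") names(obs) else character(0)
  )
}

diplotypeProbabilityVec <- function(a1, a2, freqs) {
  f1 <- unname(freqs[a1])
  f2 <- unname(freqs[a2])
  ifelse(a1 == a2, f1 * f2, 2 * f1 * f2)
}

#' Hardy--Weinberg probability of a diplotype
#'
#' `f1 * f2` for homozygous pairs and `2 * f1 * f2` for heterozygous pairs,
#' using the panel's per-allele frequencies for the chosen population.
#' Alleles with no published frequency carry the panel's floor frequency, so
#' any pair containing one has probability at most `2 * epsilon`.
#'
#' @param pair character vector of two star-allele names.
#' @param gene gene symbol.
#' @param population population label.
#' @param panel a [PgxPanel-class] object.
#' @return A single probability.
#' @examples
#' panel <- loadPanel()
#' diplotypeProbability(c("*1", "*2"), "CYP2C19", "Eur", panel)
#' @export
diplotypeProbability <- function(pair, gene, population, panel) {
  stopifnot(length(pair) == 2L)
  freqs <- alleleFrequency(panel, gene, population)
  bad <- setdiff(pair, names(freqs))
  if (length(bad) > 0L) {
    stop("allele(s) without frequency for ", gene, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  diplotypeProbabilityVec(pair[1L], pair[2L], freqs)
}

#' Rank candidate diplotypes and flag the most probable
#'
#' Sorts a [GeneDiplotypes-class] candidate table by descending probability,
#' breaking ties deterministically by ascending star-number order of the pair
#' (then by name), and flags the first candidate as `most_probable`.
#'
#' @param gd a [GeneDiplotypes-class] object.
#' @return The same object with candidates sorted and flagged.
#' @export
rankAndFlag <- function(gd) {
  gd@candidates <- rankCandidates(gd@candidates)
  gd
}

rankCandidates <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  o <- order(-cand$probability,
             starNumber(cand$allele1), starSuffix(cand$allele1),
             starNumber(cand$allele2), starSuffix(cand$allele2))
  cand <- cand[o, , drop = FALSE]
  rownames(cand) <- NULL
  cand$most_probable <- c(TRUE, rep(FALSE, nrow(cand) - 1L))
  cand
}

#' Call diplotypes for a cohort across all panel genes
#'
#' Convenience driver: runs [enumerateDiplotypes()] for every sample and gene
#' and stacks the results into the long "assigned diplotypes" table.
#'
#' @param sgList list of [SampleGenotypes-class].
#' @param panel a [PgxPanel-class] object.
#' @param population population label.
#' @param genes genes to call (default: all panel genes).
#' @return data.frame: `sample`, `gene`, `diplotype`, `allele1`, `allele2`,
#'   `probability`, `most_probable`, `status`.
#' @export
callDiplotypes <- function(sgList, panel, population = "Eur",
                           genes = panelGenes(panel)) {
  out <- list()
  for (sg in sgList) {
    for (g in genes) {
      gd <- enumerateDiplotypes(sg, g, panel, population)
      cand <- gd@candidates
      if (nrow(cand) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          sample = sg@sample, gene = g, diplotype = NA_character_,
          allele1 = NA_character_, allele2 = NA_character_,
          probability = NA_real_, most_probable = FALSE, status = gd@status,
          stringsAsFactors = FALSE
        )
      } else {
        out[[length(out) + 1L]] <- data.frame(
          sample = sg@sample, gene = g, diplotype = cand$diplotype,
          allele1 = cand$allele1, allele2 = cand$allele2,
          probability = cand$probability, most_probable = cand$most_probable,
          status = gd@status, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
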