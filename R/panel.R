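#' Load a bundled genotyping panel and its reference knowledge
#'
#' Reads the panel definition (assayed SNPs and the star alleles they tag),
#' the per-gene allele inventory, per-allele population frequencies, allele
#' function classes, phenotype lookup tables, and the drug--gene guideline map,
#' and assembles them into a validated [PgxPanel-class] object. Alleles with no
#' published frequency in a population are floored at `epsilon`; the reference
#' allele `*1` gets frequency `1 - sum(other alleles)` per gene and population.
#'
#' The bundled resource `"neuro"` is the 39-SNP / 5-gene CYP panel
#' (CYP2B6, CYP2C19, CYP2C9, CYP2D6, CYP3A5) used for neuropsychiatric
#' pharmacogenetic profiling.
#'
#' @param resource name of a bundled panel (currently `"neuro"`), or the path
#'   of a directory holding the reference TSVs with the bundled file names.
#' @param epsilon frequency floor for alleles with no published estimate.
#' @return A [PgxPanel-class] object.
#' @examples
#' panel <- loadPanel()
#' panel
#' length(panelGenes(panel))
#' @export
loadPanel <- function(resource = "neuro", epsilon = 1e-6) {
  stopifnot(is.character(resource), length(resource) == 1L)
  if (dir.exists(resource)) {
    dir <- resource
  } else if (identical(resource, "neuro")) {
    dir <- system.file("extdata", package = "cypstar")
  } else {
    stop("unknown panel resource '", resource, "'; bundled panels: \"neuro\"",
         call. = FALSE)
  }

  snps <- readRefTable(file.path(dir, "panel_snps.tsv"))
  alleles <- readRefTable(file.path(dir, "star_alleles.tsv"))
  freqWide <- readRefTable(file.path(dir, "allele_frequencies.tsv"))
  funs <- readRefTable(file.path(dir, "allele_functions.tsv"))
  dipClasses <- readRefTable(file.path(dir, "diplotype_classes.tsv"))
  bins <- readRefTable(file.path(dir, "cyp2d6_activity_bins.tsv"))
  drugs <- readRefTable(file.path(dir, "drug_gene_map.tsv"))
  guide <- readRefTable(file.path(dir, "guideline_status.tsv"))
  rules <- readRefTable(file.path(dir, "phenoconversion_rules.tsv"))

  pops <- setdiff(names(freqWide), c("gene", "allele"))
  freqs <- expandFrequencies(freqWide, alleles, pops, epsilon)

  panel <- new("PgxPanel",
    snps = snps, alleles = alleles, frequencies = freqs, functions = funs,
    diplotypeClasses = dipClasses, activityBins = bins, drugs = drugs,
    guidelines = guide, phenoconversionRules = rules, populations = pops,
    epsilon = epsilon, cache = list()
  )
  violations <- validatePanel(panel)
  if (length(violations) > 0L) {
    stop("panel '", resource, "' failed validation:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  panel@cache <- buildPanelCache(panel)
  panel
}

# Long-format frequency table, complete over callable alleles x populations:
# published values kept, unpublished floored at epsilon, *1 derived by
# subtraction so each (gene, population) column sums to 1.
expandFrequencies <- function(freqWide, alleles, pops, epsilon) {
  out <- list()
  for (g in unique(alleles$gene)) {
    inv <- alleles$allele[alleles$gene == g & alleles$callable]
    sub <- freqWide[freqWide$gene == g, , drop = FALSE]
    if (any(sub$allele == "*1")) {
      stop("frequency table must not list *1 (it is derived); gene ", g,
           call. = FALSE)
    }
    for (p in pops) {
      f <- stats::setNames(rep(epsilon, length(inv)), inv)
      known <- sub[!is.na(sub[[p]]), c("allele", p)]
      known <- known[known$allele %in% inv, , drop = FALSE]
      f[known$allele] <- known[[p]]
      f["*1"] <- 1 - sum(f[names(f) != "*1"])
      if (f["*1"] < 0) {
        stop("frequencies for ", g, " / ", p, " exceed 1", call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, allele = inv, population = p, frequency = unname(f[inv]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Check a panel against its structural invariants
#'
#' Returns human-readable violation messages instead of raising errors, so
#' that edited reference tables can be diagnosed in one pass. An empty result
#' means the panel is internally consistent: five genes, 39 distinct SNPs,
#' every allele tagged by a SNP present in the inventory, alt bases distinct
#' from reference bases, frequencies within \[0, 1\] summing to at most 1 per
#' gene and population.
#'
#' @param panel a [PgxPanel-class] object.
#' @return Character vector of violations (empty if the panel validates).
#' @examples
#' validatePanel(loadPanel())
#' @export
validatePanel <- function(panel) {
  msg <- character()
  snps <- panel@snps
  alleles <- panel@alleles

  genes <- sort(unique(alleles$gene))
  expected <- c("CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A5")
  if (!identical(genes, expected)) {
    msg <- c(msg, paste("panel genes must be", paste(expected, collapse = ", "),
                        "- found:", paste(genes, collapse = ", ")))
  }
  if (length(unique(snps$rsid)) != 39L) {
    msg <- c(msg, paste("panel must contain 39 distinct rsIDs; found",
                        length(unique(snps$rsid))))
  }
  # an rsID belongs to exactly one gene
  byGene <- unique(snps[, c("gene", "rsid")])
  dup <- byGene$rsid[duplicated(byGene$rsid)]
  if (length(dup) > 0L) {
    msg <- c(msg, paste("rsID assigned to more than one gene:",
                        paste(unique(dup), collapse = ", ")))
  }
  # one row per (rsid, alt)
  key <- paste(snps$rsid, snps$alt_base)
  if (anyDuplicated(key)) {
    msg <- c(msg, paste("duplicated (rsID, alt base) row:",
                        paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  bad <- snps$alt_base == snps$ref_base
  if (any(bad)) {
    msg <- c(msg, paste("alt base equals ref base at:",
                        paste(snps$rsid[bad], collapse = ", ")))
  }
  empty <- !nzchar(snps$tagged_alleles)
  if (any(empty)) {
    msg <- c(msg, paste("SNP tags no allele:", paste(snps$rsid[empty], collapse = ", ")))
  }
  # every tagged allele must be inventoried for that SNP's gene
  for (i in seq_len(nrow(snps))) {
    tagged <- strsplit(snps$tagged_alleles[i], ",", fixed = TRUE)[[1L]]
    inv <- alleles$allele[alleles$gene == snps$gene[i]]
    missing <- setdiff(tagged, inv)
    if (length(missing) > 0L) {
      msg <- c(msg, paste0("SNP ", snps$rsid[i], " (", snps$gene[i],
                           ") tags uninventoried allele(s): ",
                           paste(missing, collapse = ", ")))
    }
  }
  # allele inventory unique per gene, *1 present and callable
  for (g in unique(alleles$gene)) {
    inv <- alleles$allele[alleles$gene == g]
    if (anyDuplicated(inv)) {
      msg <- c(msg, paste0("duplicated allele name(s) in ", g, ": ",
                           paste(unique(inv[duplicated(inv)]), collapse = ", ")))
    }
    if (!"*1" %in% inv) msg <- c(msg, paste0("reference allele *1 missing for ", g))
  }
  # frequencies
  fr <- panel@frequencies
  if (nrow(fr) > 0L) {
    if (any(fr$frequency < 0 | fr$frequency > 1)) {
      msg <- c(msg, "allele frequencies must lie in [0, 1]")
    }
    sums <- tapply(fr$frequency, paste(fr$gene, fr$population), sum)
    if (any(sums > 1 + 1e-9)) {
      msg <- c(msg, paste("frequencies sum to more than 1 for:",
                          paste(names(sums)[sums > 1 + 1e-9], collapse = ", ")))
    }
  }
  msg
}

#' Per-gene star-allele definition matrix
#'
#' Inverts the panel's SNP table: star allele `A`'s defining variants are
#' exactly the non-ancillary panel SNPs whose tagged-allele list contains `A`,
#' each with the alt base `A` carries there. The reference allele `*1` maps to
#' an empty set. Alleles are thus defined at panel resolution as the
#' conjunction of their tag SNPs, with the reference base everywhere else.
#'
#' @param panel a [PgxPanel-class] object.
#' @param gene gene symbol (must be a panel gene).
#' @return Named list: allele name -> named character vector (rsID -> alt
#'   base); `*1` maps to an empty vector. Only callable alleles are included.
#' @examples
#' defs <- buildDefinitionMatrix(loadPanel(), "CYP2C19")
#' defs[["*2"]]   # c(rs4244285 = "A")
#' defs[["*1"]]   # empty
#' @export
buildDefinitionMatrix <- function(panel, gene) {
  assertPanelGene(panel, gene)
  snps <- panel@snps[panel@snps$gene == gene & !panel@snps$ancillary, , drop = FALSE]
  inv <- panel@alleles[panel@alleles$gene == gene & panel@alleles$callable, , drop = FALSE]
  defs <- stats::setNames(
    rep(list(stats::setNames(character(0), character(0))), nrow(inv)),
    inv$allele
  )
  for (i in seq_len(nrow(snps))) {
    tagged <- strsplit(snps$tagged_alleles[i], ",", fixed = TRUE)[[1L]]
    for (a in tagged) {
      if (!a %in% names(defs)) next   # uncallable allele (e.g. CYP2D6 *5)
      v <- defs[[a]]
      if (snps$rsid[i] %in% names(v)) {
        stop("allele ", a, " (", gene, ") tagged by two alt bases at ",
             snps$rsid[i], call. = FALSE)
      }
      v[snps$rsid[i]] <- snps$alt_base[i]
      defs[[a]] <- v
    }
  }
  if (length(defs[["*1"]]) != 0L) {
    stop("reference allele *1 must have no defining variants (", gene, ")",
         call. = FALSE)
  }
  defs
}

# Precompute, per gene: callable allele inventory, per-allele base matrix over
# the gene's constraint SNPs, the unordered allele-pair index, and each pair's
# expected genotype key per SNP. Enumeration then reduces to vector
# comparisons against the observed genotype keys.
buildPanelCache <- function(panel) {
  cache <- list()
  for (g in panelGenes(panel)) {
    defs <- buildDefinitionMatrix(panel, g)
    allelesG <- names(defs)[orderStarAlleles(names(defs))]
    snpsG <- unique(panel@snps$rsid[panel@snps$gene == g & !panel@snps$ancillary])
    refG <- vapply(snpsG, function(s) {
      panel@snps$ref_base[match(s, panel@snps$rsid)]
    }, character(1))

    base <- matrix(rep(refG, each = length(allelesG)),
                   nrow = length(allelesG), ncol = length(snpsG),
                   dimnames = list(allelesG, snpsG))
    for (a in allelesG) {
      v <- defs[[a]]
      if (length(v) > 0L) base[a, names(v)] <- unname(v)
    }

    n <- length(allelesG)
    idx1 <- rep(seq_len(n), times = n - seq_len(n) + 1L)
    idx2 <- unlist(lapply(seq_len(n), function(i) i:n), use.names = FALSE)
    keys <- matrix("", nrow = length(idx1), ncol = length(snpsG),
                   dimnames = list(NULL, snpsG))
    for (s in seq_along(snpsG)) {
      b1 <- base[idx1, s]
      b2 <- base[idx2, s]
      swap <- ifelse(b1 == "-", "", b1) > ifelse(b2 == "-", "", b2)
      keys[, s] <- ifelse(swap, paste0(b2, "/", b1), paste0(b1, "/", b2))
    }
    cache[[g]] <- list(
      alleles = allelesG, defs = defs, snps = snpsG, ref = refG, base = base,
      pair1 = allelesG[idx1], pair2 = allelesG[idx2], keys = keys
    )
  }
  cache
}

geneCache <- function(panel, gene) {
  assertPanelGene(panel, gene)
  cc <- panel@cache[[gene]]
  if (is.null(cc)) {
    # panel constructed or mutated without loadPanel(); build on the fly
    cc <- buildPanelCache(panel)[[gene]]
  }
  cc
}

assertPanelGene <- function(panel, gene) {
  stopifnot(is.character(gene), length(gene) == 1L)
  if (!gene %in% panelGenes(panel)) {
    stop("'", gene, "' is not a panel gene (",
         paste(panelGenes(panel), collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Size of the cross-gene diplotype combination space
#'
#' The number of distinct cross-gene diplotype combinations the panel can in
#' principle assign: the product over genes of `n (n + 1) / 2`, where `n` is
#' the number of callable star alleles of the gene (unordered pairs with
#' replacement). For the bundled panel this exceeds five million by three
#' orders of magnitude, which is why per-sample enumeration works gene by
#' gene rather than over the product space.
#'
#' @param panel a [PgxPanel-class] object.
#' @return A single number (exact integer arithmetic in double precision).
#' @examples
#' combinationSpaceSize(loadPanel())
#' @export
combinationSpaceSize <- function(panel) {
  counts <- vapply(panelGenes(panel), function(g) {
    sum(panel@alleles$gene == g & panel@alleles$callable)
  }, numeric(1))
  prod(counts * (counts + 1) / 2)
}

#' Look up allele frequencies for one gene and population
#'
#' @param panel a [PgxPanel-class] object.
#' @param gene gene symbol.
#' @param population population label (see [populations()]).
#' @return Named numeric vector of per-allele frequencies.
#' @export
alleleFrequency <- function(panel, gene, population) {
  assertPanelGene(panel, gene)
  if (!population %in% panel@populations) {
    stop("unknown population '", population, "'; valid labels: ",
         paste(panel@populations, collapse = ", "), call. = FALSE)
  }
  fr <- panel@frequencies
  sub <- fr[fr$gene == gene & fr$population == population, , drop = FALSE]
  stats::setNames(sub$frequency, sub$allele)
}
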