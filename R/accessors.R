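#' Accessors for PgxPanel objects
#'
#' Read-only views of the reference knowledge held by a [PgxPanel-class]
#' object: the assayed SNPs, the star-allele inventory, frequencies, function
#' classes, the drug--gene map, guideline status flags, population labels and
#' gene symbols.
#'
#' @param x a [PgxPanel-class] object.
#' @param gene optional gene symbol to restrict the result.
#' @param ... unused.
#' @return A data.frame (or character vector for `populations()` and
#'   `panelGenes()`).
#' @name PgxPanel-accessors
NULL

#' @rdname PgxPanel-accessors
#' @export
setMethod("panelSNPs", "PgxPanel", function(x, gene = NULL, ...) {
  out <- x@snps
  if (!is.null(gene)) out <- out[out$gene == gene, , drop = FALSE]
  out
})

#' @rdname PgxPanel-accessors
#' @export
setMethod("starAlleles", "PgxPanel", function(x, gene = NULL, ...) {
  out <- x@alleles
  if (!is.null(gene)) out <- out[out$gene == gene, , drop = FALSE]
  out
})

#' @rdname PgxPanel-accessors
#' @export
setMethod("alleleFrequencies", "PgxPanel", function(x, gene = NULL, ...) {
  out <- x@frequencies
  if (!is.null(gene)) out <- out[out$gene == gene, , drop = FALSE]
  out
})

#' @rdname PgxPanel-accessors
#' @export
setMethod("alleleFunctions", "PgxPanel", function(x, gene = NULL, ...) {
  out <- x@functions
  if (!is.null(gene)) out <- out[out$gene == gene, , drop = FALSE]
  out
})

#' @rdname PgxPanel-accessors
#' @export
setMethod("drugGeneMap", "PgxPanel", function(x, ...) x@drugs)

#' @rdname PgxPanel-accessors
#' @export
setMethod("guidelineStatus", "PgxPanel", function(x, ...) x@guidelines)

#' @rdname PgxPanel-accessors
#' @export
setMethod("populations", "PgxPanel", function(x, ...) x@populations)

#' @rdname PgxPanel-accessors
#' @export
setMethod("panelGenes", "PgxPanel", function(x, ...) {
  sort(unique(x@alleles$gene))
})

#' Accessors for SampleGenotypes objects
#'
#' @param x a [SampleGenotypes-class] object.
#' @param ... unused.
#' @name SampleGenotypes-accessors
NULL

#' @rdname SampleGenotypes-accessors
#' @export
setMethod("sampleID", "SampleGenotypes", function(x, ...) x@sample)

#' @rdname SampleGenotypes-accessors
#' @export
setMethod("genotypeCalls", "SampleGenotypes", function(x, ...) x@calls)

#' Accessors for GeneDiplotypes objects
#'
#' `candidates()` returns the full candidate table, `mostProbable()` the single
#' flagged top diplotype label (or `NA` for a no-call), `callStatus()` the
#' call status.
#'
#' @param x a [GeneDiplotypes-class] object.
#' @param ... unused.
#' @name GeneDiplotypes-accessors
NULL

#' @rdname GeneDiplotypes-accessors
#' @export
setMethod("candidates", "GeneDiplotypes", function(x, ...) x@candidates)

#' @rdname GeneDiplotypes-accessors
#' @export
setMethod("callStatus", "GeneDiplotypes", function(x, ...) x@status)

#' @rdname GeneDiplotypes-accessors
#' @export
setMethod("mostProbable", "GeneDiplotypes", function(x, ...) {
  if (nrow(x@candidates) == 0L) return(NA_character_)
  x@candidates$diplotype[x@candidates$most_probable][1L]
})

setMethod("show", "PgxPanel", function(object) {
  nsnp <- length(unique(object@snps$rsid))
  genes <- panelGenes(object)
  cat("PgxPanel with", nsnp, "SNPs across", length(genes), "genes\n")
  for (g in genes) {
    inv <- object@alleles[object@alleles$gene == g, ]
    cat(sprintf("  %-8s %2d SNPs, %3d alleles (%d callable)\n", g,
                length(unique(object@snps$rsid[object@snps$gene == g])),
                nrow(inv), sum(inv$callable)))
  }
  cat("  populations:", paste(object@populations, collapse = ", "), "\n")
  cat("  drugs:", nrow(object@drugs), "\n")
})

setMethod("show", "SampleGenotypes", function(object) {
  cl <- object@calls
  cat("SampleGenotypes for sample", object@sample, "\n")
  cat(sprintf("  %d SNPs observed (%d called, %d missing)\n",
              nrow(cl), sum(!cl$missing), sum(cl$missing)))
})

setMethod("show", "GeneDiplotypes", function(object) {
  cat(sprintf("GeneDiplotypes: %s / %s [%s, population %s]\n",
              object@sample, object@gene, object@status, object@population))
  nc <- nrow(object@candidates)
  cat(" ", nc, "candidate diplotype(s)\n")
  if (nc > 0L) {
    top <- utils::head(object@candidates, 3L)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("   %s%-10s p = %.4g\n",
                  if (top$most_probable[i]) "* " else "  ",
                  top$diplotype[i], top$probability[i]))
    }
    if (nc > 3L) cat("   ...\n")
  }
})
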