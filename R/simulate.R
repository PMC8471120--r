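#' Simulate a genotyped cohort with known true diplotypes
#'
#' Draws, for each sample and gene, two star alleles independently from the
#' panel's population frequency distribution (Hardy--Weinberg), renders the
#' implied genotype at every panel SNP from the pair's allele signatures, and
#' masks each SNP independently with probability `1 - callRate` (a no-call
#' regime; genotyping errors are off by default but available via
#' `miscallRate` for robustness studies). Output rows use the standard
#' 4-column input format, so the simulator exercises the same parser and
#' engine paths as real data. Fully reproducible given `seed`.
#'
#' @param n number of samples.
#' @param panel a [PgxPanel-class] object.
#' @param population population label whose frequencies drive the sampling.
#' @param callRate per-SNP probability of receiving a call, in (0, 1]. The
#'   default 0.941 mirrors the average call rate of the panel's published
#'   100-sample validation run.
#' @param seed integer seed.
#' @param miscallRate per-SNP probability of replacing a called genotype with
#'   a random wrong one (default 0).
#' @param genes genes to simulate (default: all panel genes).
#' @return List of simulated samples; each element has `sample` (identifier),
#'   `truth` (named list gene -> canonical allele pair), `rows` (the
#'   4-column genotype table) and `seed`.
#' @examples
#' panel <- loadPanel()
#' sims <- simulateCohort(3, panel = panel, seed = 7)
#' sims[[1]]$truth$CYP2C19
#' @export
simulateCohort <- function(n, panel, population = "Eur", callRate = 0.941,
                           seed = 1L, miscallRate = 0,
                           genes = panelGenes(panel)) {
  stopifnot(n >= 1L)
  if (!is.numeric(callRate) || callRate <= 0 || callRate > 1) {
    stop("callRate must lie in (0, 1]", call. = FALSE)
  }
  if (!population %in% panel@populations) {
    stop("unknown population '", population, "'; valid labels: ",
         paste(panel@populations, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  freqs <- lapply(stats::setNames(genes, genes), alleleFrequency,
                  panel = panel, population = population)
  snpRows <- panel@snps[panel@snps$gene %in% genes, , drop = FALSE]
  snpTab <- unique(snpRows[, c("gene", "rsid", "ref_base")])

  out <- vector("list", n)
  width <- max(3L, nchar(as.character(n)))
  for (k in seq_len(n)) {
    id <- sprintf("S%0*d", width, k)
    truth <- list()
    rows <- list()
    for (g in genes) {
      cc <- geneCache(panel, g)
      f <- freqs[[g]]
      pair <- sample(names(f), 2L, replace = TRUE, prob = f)
      pair <- canonicalAllelePair(pair[1L], pair[2L])
      truth[[g]] <- pair

      gsnps <- snpTab[snpTab$gene == g, , drop = FALSE]
      geno <- character(nrow(gsnps))
      for (i in seq_len(nrow(gsnps))) {
        s <- gsnps$rsid[i]
        if (s %in% cc$snps) {
          b <- sortBasePair(cc$base[pair[1L], s], cc$base[pair[2L], s])
        } else {
          b <- c(gsnps$ref_base[i], gsnps$ref_base[i])  # ancillary: hom ref
        }
        if (miscallRate > 0 && stats::runif(1) < miscallRate) {
          alts <- allowedBases(panel, s)
          b <- sample(alts, 2L, replace = TRUE)
          b <- sortBasePair(b[1L], b[2L])
        }
        geno[i] <- paste0(b[1L], "/", b[2L])
      }
      called <- stats::runif(nrow(gsnps)) <= callRate
      geno[!called] <- ""
      rows[[g]] <- data.frame(
        Sample = id, Gene = g, rsID = gsnps$rsid, Genotype = geno,
        stringsAsFactors = FALSE
      )
    }
    out[[k]] <- list(sample = id, truth = truth,
                     rows = do.call(rbind, rows), seed = seed)
  }
  for (k in seq_len(n)) rownames(out[[k]]$rows) <- NULL
  out
}

#' Stack a simulated cohort into one pooled genotype table
#'
#' @param sims list from [simulateCohort()].
#' @return data.frame in the 4-column input format covering all samples.
#' @export
cohortGenotypeTable <- function(sims) {
  tab <- do.call(rbind, lapply(sims, `[[`, "rows"))
  rownames(tab) <- NULL
  tab
}

#' Recovery and containment rates of diplotype calls against simulation truth
#'
#' For each gene: the fraction of samples whose most-probable call equals the
#' true simulated diplotype (top-1 recovery), and the fraction whose true
#' diplotype appears anywhere in the candidate set (containment; 1 by
#' construction when nothing in the data contradicts the truth).
#'
#' @param sims list from [simulateCohort()].
#' @param calls data.frame from [callDiplotypes()] run on the sims' tables.
#' @return data.frame: `gene`, `n`, `top1_recovery`, `containment`.
#' @export
recoveryRate <- function(sims, calls) {
  simIDs <- vapply(sims, `[[`, character(1), "sample")
  if (!all(simIDs %in% calls$sample)) {
    stop("calls lack sample(s): ",
         paste(setdiff(simIDs, calls$sample), collapse = ", "), call. = FALSE)
  }
  genes <- unique(calls$gene)
  byKey <- split(seq_len(nrow(calls)),
                 paste(calls$sample, calls$gene, sep = "\r"))
  out <- list()
  for (g in genes) {
    top1 <- 0L
    contained <- 0L
    total <- 0L
    for (sim in sims) {
      if (!g %in% names(sim$truth)) next
      truthLabel <- paste(sim$truth[[g]], collapse = "/")
      sub <- calls[byKey[[paste(sim$sample, g, sep = "\r")]], , drop = FALSE]
      total <- total + 1L
      if (truthLabel %in% sub$diplotype) contained <- contained + 1L
      best <- sub$diplotype[sub$most_probable]
      if (length(best) == 1L && !is.na(best) && best == truthLabel) top1 <- top1 + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = g, n = total, top1_recovery = top1 / total,
      containment = contained / total, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
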