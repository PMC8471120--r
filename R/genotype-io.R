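#' Canonicalise a raw genotype string
#'
#' Splits an unphased genotype on its `/` separator, trims whitespace,
#' uppercases, and returns the two bases in canonical order (`-` sorts before
#' letters, then lexicographic). Phase is never inferred from input order:
#' `"G/A"` and `"A/G"` denote the same genotype. Deletions are coded `-`
#' (`-/-` or `A/-`); multi-base calls such as `CTT/CTT` are allowed.
#'
#' @param raw a single genotype string containing exactly one `/`.
#' @return Character vector of length 2 (the canonical base pair).
#' @examples
#' normalizeGenotypeString("t/c")   # "C" "T"
#' normalizeGenotypeString("A/-")   # "-" "A"
#' @export
normalizeGenotypeString <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  parts <- strsplit(raw, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || lengths(regmatches(raw, gregexpr("/", raw, fixed = TRUE))) != 1L) {
    stop("genotype '", raw, "' must contain exactly one '/' separator",
         call. = FALSE)
  }
  parts <- toupper(trimws(parts))
  if (any(!nzchar(parts))) {
    stop("genotype '", raw, "' has an empty side", call. = FALSE)
  }
  sortBasePair(parts[1L], parts[2L])
}

#' Parse a 4-column genotype table into per-sample genotype objects
#'
#' Reads the standard input format -- four columns `Sample`, `Gene`, `rsID`,
#' `Genotype` (header match case-insensitive), comma- or tab-delimited -- and
#' returns one [SampleGenotypes-class] object per distinct sample. Multiple
#' samples may share one file. Rows with an empty or `NA` genotype become
#' explicit missing calls; rsIDs not on the panel are skipped with a warning;
#' panel SNPs absent from the file are treated as missing downstream. Observed
#' bases are checked against the panel's reference and alternate bases (plus
#' `-` for deletions); anything else is an error naming the rsID.
#'
#' @param source path to a `.csv`/`.tsv`/`.txt` file, or a data.frame already
#'   holding the four columns.
#' @param panel a [PgxPanel-class] object.
#' @return Named list of [SampleGenotypes-class], one per sample, in order of
#'   first appearance.
#' @examples
#' panel <- loadPanel()
#' tab <- data.frame(Sample = "S1", Gene = "CYP2C19",
#'                   rsID = "rs4244285", Genotype = "G/A")
#' parseGenotypeTable(tab, panel)
#' @export
parseGenotypeTable <- function(source, panel) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("input file not found: ", source, call. = FALSE)
    sep <- sniffDelimiter(source)
    raw <- data.table::fread(source, sep = sep, header = TRUE,
                             colClasses = "character", data.table = FALSE,
                             na.strings = NULL)
  } else if (is.data.frame(source)) {
    raw <- as.data.frame(lapply(source, as.character), stringsAsFactors = FALSE)
  } else {
    stop("source must be a file path or a data.frame", call. = FALSE)
  }

  names(raw) <- tolower(trimws(names(raw)))
  need <- c("sample", "gene", "rsid", "genotype")
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0L) {
    stop("genotype table lacks required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, need]
  raw$sample <- trimws(raw$sample)
  raw$gene <- trimws(raw$gene)
  raw$rsid <- trimws(raw$rsid)

  known <- unique(panel@snps$rsid)
  unknown <- setdiff(unique(raw$rsid), known)
  if (length(unknown) > 0L) {
    warning("skipping ", length(unknown), " rsID(s) not on the panel: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    raw <- raw[raw$rsid %in% known, , drop = FALSE]
  }

  samples <- unique(raw$sample)
  chunks <- split(raw, factor(raw$sample, levels = samples))
  out <- vector("list", length(samples))
  names(out) <- samples
  for (s in samples) {
    calls <- parseSampleRows(s, chunks[[s]], panel)
    out[[s]] <- new("SampleGenotypes", sample = s, calls = calls)
  }
  out
}

parseSampleRows <- function(sample, rows, panel) {
  snpGene <- panel@snps$gene[match(rows$rsid, panel@snps$rsid)]
  geno <- trimws(rows$genotype)
  isMissing <- is.na(geno) | !nzchar(geno) | toupper(geno) %in% c("NA", "N/A")

  base1 <- rep(NA_character_, nrow(rows))
  base2 <- rep(NA_character_, nrow(rows))
  for (i in which(!isMissing)) {
    pair <- normalizeGenotypeString(geno[i])
    allowed <- allowedBases(panel, rows$rsid[i])
    bad <- setdiff(pair, allowed)
    if (length(bad) > 0L) {
      stop("sample ", sample, ", ", rows$rsid[i], ": base(s) ",
           paste(bad, collapse = ", "), " not among panel bases {",
           paste(allowed, collapse = ", "), "}", call. = FALSE)
    }
    base1[i] <- pair[1L]
    base2[i] <- pair[2L]
  }

  calls <- data.frame(
    gene = snpGene, rsid = rows$rsid, base1 = base1, base2 = base2,
    missing = isMissing, stringsAsFactors = FALSE
  )
  # collapse duplicates: identical repeats allowed, conflicts are errors
  if (anyDuplicated(calls$rsid)) {
    keyed <- split(calls, calls$rsid)
    calls <- do.call(rbind, lapply(keyed, function(d) {
      u <- unique(d[, c("base1", "base2", "missing")])
      if (nrow(u) > 1L) {
        stop("sample ", sample, ": conflicting genotypes for ", d$rsid[1L],
             call. = FALSE)
      }
      d[1L, , drop = FALSE]
    }))
    rownames(calls) <- NULL
  }
  calls
}

allowedBases <- function(panel, rsid) {
  rows <- panel@snps[panel@snps$rsid == rsid, , drop = FALSE]
  unique(c(rows$ref_base, rows$alt_base, "-"))
}

sniffDelimiter <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "tab")) return("\t")
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Serialize per-sample genotypes back to the 4-column table
#'
#' Inverse of [parseGenotypeTable()]: writes (or returns) the canonical
#' `Sample, Gene, rsID, Genotype` table. Missing calls get an empty genotype
#' field. Round-tripping through this writer and the parser is lossless.
#'
#' @param sgList a list of [SampleGenotypes-class] (or a single object).
#' @param path optional output path (`.tsv` or `.csv` by extension); if
#'   omitted the table is returned invisibly only.
#' @return The table as a data.frame, invisibly.
#' @export
writeGenotypeTable <- function(sgList, path = NULL) {
  if (is(sgList, "SampleGenotypes")) sgList <- list(sgList)
  tab <- do.call(rbind, lapply(sgList, function(sg) {
    cl <- sg@calls
    data.frame(
      Sample = sg@sample, Gene = cl$gene, rsID = cl$rsid,
      Genotype = ifelse(cl$missing, "", paste0(cl$base1, "/", cl$base2)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  if (!is.null(path)) {
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

#' Genotyping call rate for one sample
#'
#' The call rate is the fraction of panel SNPs that received a genotype call:
#' `called / total`, where `total` counts every SNP on the panel (39 for the
#' bundled panel) and `called` the sample's non-missing calls. A run passes QC
#' when the rate strictly exceeds the threshold (default 0.90).
#'
#' @param sg a [SampleGenotypes-class] object.
#' @param panel a [PgxPanel-class] object.
#' @param threshold QC pass threshold; `pass` is `rate > threshold`.
#' @return One-row data.frame: `sample`, `called`, `total`, `rate`, `pass`.
#' @examples
#' panel <- loadPanel()
#' sims <- simulateCohort(1, panel = panel, seed = 1, callRate = 1)
#' sg <- parseGenotypeTable(sims[[1]]$rows, panel)[[1]]
#' computeCallRate(sg, panel)   # 39/39, pass
#' @export
computeCallRate <- function(sg, panel, threshold = 0.90) {
  total <- length(unique(panel@snps$rsid))
  called <- sum(!sg@calls$missing & sg@calls$rsid %in% panel@snps$rsid)
  rate <- called / total
  data.frame(sample = sg@sample, called = called, total = total,
             rate = rate, pass = rate > threshold, stringsAsFactors = FALSE)
}

#' Call-rate QC table for a list of samples
#'
#' @param sgList list of [SampleGenotypes-class].
#' @inheritParams computeCallRate
#' @return data.frame with one row per sample.
#' @export
callRateTable <- function(sgList, panel, threshold = 0.90) {
  out <- do.call(rbind, lapply(sgList, computeCallRate, panel = panel,
                               threshold = threshold))
  rownames(out) <- NULL
  out
}
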