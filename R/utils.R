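# Internal helpers: star-allele name ordering and base-pair canonicalisation.

# Numeric part of a star-allele name ("*17" -> 17); suffix letters (rare,
# e.g. "*4A") sort after the number.
starNumber <- function(x) {
  suppressWarnings(as.numeric(sub("^\\*([0-9]+).*$", "\\1", x)))
}

starSuffix <- function(x) {
  sub("^\\*[0-9]+", "", x)
}

# Order star-allele names by numeric star order, then suffix.
orderStarAlleles <- function(x) {
  order(starNumber(x), starSuffix(x))
}

# Canonical unordered pair of allele names (lower star number first).
canonicalAllelePair <- function(a, b) {
  if (orderStarAlleles(c(a, b))[1L] == 1L) c(a, b) else c(b, a)
}

diplotypeLabel <- function(a, b) {
  p <- canonicalAllelePair(a, b)
  paste(p, collapse = "/")
}

# Canonical unordered base pair: "-" sorts before letters, then lexicographic
# (C locale), so "A/-" -> c("-", "A") and "t/c" -> c("C", "T").
sortBasePair <- function(b1, b2) {
  key <- function(b) if (b == "-") "" else b
  if (key(b1) <= key(b2)) c(b1, b2) else c(b2, b1)
}

genotypeKey <- function(b1, b2) {
  paste(sortBasePair(b1, b2), collapse = "/")
}

# Read a bundled/ external reference TSV, skipping '#' provenance comments.
readRefTable <- function(path) {
  if (!file.exists(path)) stop("reference table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  out <- tryCatch(
    data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                      header = TRUE, na.strings = "NA", data.table = FALSE),
    error = function(e) stop("malformed reference table '", basename(path), "': ",
                             conditionMessage(e), call. = FALSE)
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
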