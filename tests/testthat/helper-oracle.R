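# Independent brute-force oracle for diplotype enumeration. Deliberately
# re-derives everything from the definition matrix and the SNP table rather
# than touching the engine's internal cache: it builds each allele's full
# haplotype base vector, forms ALL unordered allele pairs with their expected
# unordered base pair per SNP (own canonicalisation, "|" separator), and
# filters pairs against the observed genotypes.

oracleBaseKey <- function(b) ifelse(b == "-", "", b)

oracleHaplotypes <- function(panel, gene) {
  defs <- buildDefinitionMatrix(panel, gene)
  snps <- panelSNPs(panel, gene)
  snps <- snps[!snps$ancillary, , drop = FALSE]
  rsids <- unique(snps$rsid)
  ref <- vapply(rsids, function(s) snps$ref_base[match(s, snps$rsid)],
                character(1))
  lapply(defs, function(d) {
    v <- ref
    if (length(d) > 0L) v[names(d)] <- d
    v
  })
}

# All n(n+1)/2 unordered pairs with, for every SNP, the unordered pair of
# bases the two haplotypes would contribute. Built once per gene by an
# explicit double loop; reused across genotypes.
oraclePairTable <- function(panel, gene) {
  haps <- oracleHaplotypes(panel, gene)
  alleles <- names(haps)
  n <- length(alleles)
  labels <- character(n * (n + 1) / 2)
  keys <- matrix("", nrow = n * (n + 1) / 2, ncol = length(haps[[1L]]),
                 dimnames = list(NULL, names(haps[[1L]])))
  r <- 0L
  for (i in seq_len(n)) {
    h1 <- haps[[i]]
    for (j in i:n) {
      h2 <- haps[[j]]
      r <- r + 1L
      labels[r] <- paste0(alleles[i], "/", alleles[j])
      lo <- oracleBaseKey(h1) <= oracleBaseKey(h2)
      keys[r, ] <- paste0(ifelse(lo, h1, h2), "|", ifelse(lo, h2, h1))
    }
  }
  list(labels = labels, keys = keys)
}

oracleObserved <- function(sg, rsids) {
  cl <- genotypeCalls(sg)
  cl <- cl[!cl$missing & cl$rsid %in% rsids, , drop = FALSE]
  if (nrow(cl) == 0L) return(character(0))
  lo <- oracleBaseKey(cl$base1) <= oracleBaseKey(cl$base2)
  stats::setNames(
    paste0(ifelse(lo, cl$base1, cl$base2), "|", ifelse(lo, cl$base2, cl$base1)),
    cl$rsid
  )
}

bruteForceDiplotypes <- function(panel, gene, sg, pairTab = NULL) {
  if (is.null(pairTab)) pairTab <- oraclePairTable(panel, gene)
  obs <- oracleObserved(sg, colnames(pairTab$keys))
  ok <- rep(TRUE, length(pairTab$labels))
  for (s in names(obs)) ok <- ok & (pairTab$keys[, s] == obs[[s]])
  pairTab$labels[ok]
}
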