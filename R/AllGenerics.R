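#' @rdname PgxPanel-accessors
#' @export
setGeneric("panelSNPs", function(x, ...) standardGeneric("panelSNPs"))

#' @rdname PgxPanel-accessors
#' @export
setGeneric("starAlleles", function(x, ...) standardGeneric("starAlleles"))

#' @rdname PgxPanel-accessors
#' @export
setGeneric("alleleFrequencies", function(x, ...) standardGeneric("alleleFrequencies"))

#' @rdname PgxPanel-accessors
#' @export
setGeneric("alleleFunctions", function(x, ...) standardGeneric("alleleFunctions"))

#' @rdname PgxPanel-accessors
#' @export
setGeneric("drugGeneMap", function(x, ...) standardGeneric("drugGeneMap"))

#' @rdname PgxPanel-accessors
#' @export
setGeneric("guidelineStatus", function(x, ...) standardGeneric("guidelineStatus"))

#' @rdname PgxPanel-accessors
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname PgxPanel-accessors
#' @export
setGeneric("panelGenes", function(x, ...) standardGeneric("panelGenes"))

#' @rdname SampleGenotypes-accessors
#' @export
setGeneric("sampleID", function(x, ...) standardGeneric("sampleID"))

#' @rdname SampleGenotypes-accessors
#' @export
setGeneric("genotypeCalls", function(x, ...) standardGeneric("genotypeCalls"))

#' @rdname GeneDiplotypes-accessors
#' @export
setGeneric("candidates", function(x, ...) standardGeneric("candidates"))

#' @rdname GeneDiplotypes-accessors
#' @export
setGeneric("callStatus", function(x, ...) standardGeneric("callStatus"))

#' @rdname GeneDiplotypes-accessors
#' @export
setGeneric("mostProbable", function(x, ...) standardGeneric("mostProbable"))
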