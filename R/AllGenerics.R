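#' @rdname GenomeMap
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))

#' @rdname GenomeMap
#' @export
setGeneric("chrLengths", function(x) standardGeneric("chrLengths"))

#' @rdname GenomeMap
#' @export
setGeneric("markerPositions", function(x) standardGeneric("markerPositions"))

#' @rdname GenomeMap
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenomeMap
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname Population-accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname Population-accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname Population-accessors
#' @export
setGeneric("genotypes", function(x, loci = NULL) standardGeneric("genotypes"))

#' @rdname Population-accessors
#' @export
setGeneric("breedFractions", function(x) standardGeneric("breedFractions"))

#' @rdname Population-accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname Population-accessors
#' @export
setGeneric("genomeMap", function(x) standardGeneric("genomeMap"))

#' @rdname Population-accessors
#' @export
setGeneric("popLabel", function(x) standardGeneric("popLabel"))

#' @rdname QTLArchitecture-accessors
#' @export
setGeneric("qtlIndex", function(x) standardGeneric("qtlIndex"))

#' @rdname QTLArchitecture-accessors
#' @export
setGeneric("qtlEffects", function(x) standardGeneric("qtlEffects"))
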