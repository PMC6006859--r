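#' Construct a genetic map
#'
#' Default configuration mirrors the simulated genome used throughout the
#' package: six 100-cM chromosomes carrying 5000 equally spaced bi-allelic
#' markers each, a binomial map function capped at 4 crossovers per chromosome
#' per meiosis, and a reversible per-locus mutation rate of 2.5e-5. Equal
#' spacing places markers at the midpoints of a regular grid, so no marker
#' sits exactly on a chromosome boundary.
#'
#' @param nChr number of chromosomes.
#' @param chrLength chromosome length(s) in cM (recycled to \code{nChr}).
#' @param markersPerChr marker count per chromosome (recycled), ignored when
#'   \code{positions} is given.
#' @param maxCrossovers crossover cap per chromosome per meiosis.
#' @param mutationRate per-locus per-meiosis allele flip probability.
#' @param positions optional list of within-chromosome cM positions.
#' @return A [GenomeMap-class] object.
#' @examples
#' gm <- GenomeMap(nChr = 2, chrLength = 50, markersPerChr = 100)
#' nLoci(gm)
#' @export
GenomeMap <- function(nChr = 6L, chrLength = 100, markersPerChr = 5000L,
                      maxCrossovers = 4L, mutationRate = 2.5e-5,
                      positions = NULL) {
  nChr <- as.integer(nChr)
  stopifnot(nChr >= 1)
  chrLength <- rep_len(as.numeric(chrLength), nChr)
  if (is.null(positions)) {
    markersPerChr <- rep_len(as.integer(markersPerChr), nChr)
    positions <- lapply(seq_len(nChr), function(c) {
      m <- markersPerChr[c]
      (seq_len(m) - 0.5) * chrLength[c] / m
    })
  }
  new("GenomeMap", chrLength = chrLength, positions = positions,
      maxCrossovers = as.integer(maxCrossovers),
      mutationRate = as.numeric(mutationRate))
}

#' @rdname GenomeMap
#' @param x a \code{GenomeMap} (or, for \code{markerMap}, a \code{Population}).
#' @export
setMethod("nChromosomes", "GenomeMap", function(x) length(x@chrLength))

#' @rdname GenomeMap
#' @export
setMethod("chrLengths", "GenomeMap", function(x) x@chrLength)

#' @rdname GenomeMap
#' @export
setMethod("markerPositions", "GenomeMap", function(x) x@positions)

#' @rdname GenomeMap
#' @export
setMethod("nLoci", "GenomeMap", function(x) sum(vapply(x@positions, length, 1L)))

#' @describeIn GenomeMap data.frame of all loci with global index,
#'   chromosome, and within-chromosome cM position.
#' @export
setMethod("markerMap", "GenomeMap", function(x) {
  m <- vapply(x@positions, length, 1L)
  data.frame(
    locus = seq_len(sum(m)),
    chr = rep(seq_along(m), m),
    pos = unlist(x@positions, use.names = FALSE)
  )
})

setMethod("show", "GenomeMap", function(object) {
  m <- vapply(object@positions, length, 1L)
  cat("GenomeMap:", length(m), "chromosomes,", sum(m), "loci\n")
  cat("  lengths (cM):", paste(format(object@chrLength), collapse = ", "), "\n")
  cat("  crossover cap:", object@maxCrossovers,
      " mutation rate:", format(object@mutationRate), "\n")
})

# flat 0-based chromosome offsets for the C++ kernels
.chr_offsets <- function(genome) {
  m <- vapply(genome@positions, length, 1L)
  as.integer(c(0L, cumsum(m)))
}

.flat_positions <- function(genome) unlist(genome@positions, use.names = FALSE)
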