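#' Genetic map of the simulated genome
#'
#' A \code{GenomeMap} holds the chromosome lengths (cM), the ordered marker
#' positions on each chromosome, the per-meiosis crossover cap of the binomial
#' map function, and the per-locus reversible mutation rate. It is the shared
#' coordinate authority for the simulator and all downstream analyses.
#'
#' @slot chrLength numeric vector of chromosome lengths in cM.
#' @slot positions list of numeric vectors; within-chromosome marker
#'   positions in cM, strictly increasing, inside \code{[0, chrLength]}.
#' @slot maxCrossovers integer cap on crossovers per chromosome per meiosis.
#' @slot mutationRate per-locus, per-meiosis probability of an allele flip.
#'
#' @seealso [GenomeMap()]
#' @export
setClass("GenomeMap",
  representation(
    chrLength = "numeric",
    positions = "list",
    maxCrossovers = "integer",
    mutationRate = "numeric"
  )
)

setValidity("GenomeMap", function(object) {
  msg <- character()
  if (length(object@chrLength) != length(object@positions))
    msg <- c(msg, "positions list must have one element per chromosome")
  if (any(object@chrLength <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  for (c in seq_along(object@positions)) {
    p <- object@positions[[c]]
    if (length(p) && (any(diff(p) <= 0) || any(p < 0) || any(p > object@chrLength[c])))
      msg <- c(msg, sprintf("chromosome %d: positions must be strictly increasing in [0, length]", c))
  }
  if (object@maxCrossovers < 1) msg <- c(msg, "maxCrossovers must be >= 1")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' One generation's cohort of phased individuals
#'
#' A \code{Population} stores the phased haplotypes of one cohort (loci in
#' rows, haplotypes in columns; individual i owns columns 2i-1 and 2i), the
#' pedigree records of the cohort and its recorded ancestors, per-individual
#' breed-composition fractions, and the generation counter. Haplotype alleles
#' are raw bytes 0/1.
#'
#' @slot haplotypes raw matrix, loci x (2 x individuals).
#' @slot genome the [GenomeMap-class] the haplotypes are defined on.
#' @slot ids character vector of cohort individual ids.
#' @slot pedigree data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (NA for pedigree founders), \code{generation}, \code{pop}; contains the
#'   cohort plus all recorded ancestors, sorted so parents precede offspring.
#' @slot breedFractions numeric matrix (individuals x breeds) of ancestry
#'   proportions, rows summing to 1; zero columns while the population is a
#'   single undifferentiated ancestral pool.
#' @slot generation integer generation label.
#' @slot label population label (e.g. "A", "AB", "(AB)(CD)", "ADMX").
#' @export
setClass("Population",
  representation(
    haplotypes = "matrix",
    genome = "GenomeMap",
    ids = "character",
    pedigree = "data.frame",
    breedFractions = "matrix",
    generation = "integer",
    label = "character"
  )
)

setValidity("Population", function(object) {
  msg <- character()
  L <- sum(vapply(object@genome@positions, length, 1L))
  h <- object@haplotypes
  if (!is.raw(h[1])) msg <- c(msg, "haplotypes must be a raw matrix")
  if (nrow(h) != L) msg <- c(msg, "haplotype rows must match the genome's locus count")
  if (ncol(h) %% 2 != 0) msg <- c(msg, "haplotype columns must come in pairs")
  n <- ncol(h) / 2
  if (length(object@ids) != n) msg <- c(msg, "ids must match individual count")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  # allele range check on a bounded sample (full scan is costly at scale)
  probe <- h[seq_len(min(length(h), 10000L))]
  if (length(probe) && any(probe > as.raw(1)))
    msg <- c(msg, "haplotype entries must be 0/1")
  bf <- object@breedFractions
  if (ncol(bf) > 0) {
    if (nrow(bf) != n) msg <- c(msg, "breedFractions rows must match individuals")
    else if (any(abs(rowSums(bf) - 1) > 1e-12))
      msg <- c(msg, "breedFractions rows must sum to 1")
  }
  ped <- object@pedigree
  need <- c("id", "sire", "dam", "generation", "pop")
  if (!all(need %in% names(ped))) msg <- c(msg, "pedigree missing required columns")
  else {
    if (!all(object@ids %in% ped$id)) msg <- c(msg, "cohort ids missing from pedigree")
    known <- ped$id
    par <- c(ped$sire, ped$dam)
    if (!all(is.na(par) | par %in% known))
      msg <- c(msg, "every non-founder's sire and dam must be pedigree members")
  }
  if (length(msg)) msg else TRUE
})

#' Trait architecture: QTL markers and their standardized effects
#'
#' @slot qtlIndex integer global locus indices of the QTL markers.
#' @slot chr integer chromosome of each QTL.
#' @slot pos numeric within-chromosome cM position of each QTL marker.
#' @slot varFraction numeric target variance fractions (relative weights).
#' @slot effects numeric signed allele-substitution effects (NA until
#'   [standardizeEffects()] is called).
#' @slot h2 numeric target narrow-sense heritability.
#' @export
setClass("QTLArchitecture",
  representation(
    qtlIndex = "integer",
    chr = "integer",
    pos = "numeric",
    varFraction = "numeric",
    effects = "numeric",
    h2 = "numeric"
  )
)

setValidity("QTLArchitecture", function(object) {
  k <- length(object@qtlIndex)
  msg <- character()
  if (length(object@chr) != k || length(object@pos) != k ||
      length(object@varFraction) != k || length(object@effects) != k)
    msg <- c(msg, "all per-QTL slots must have equal length")
  if (any(object@varFraction <= 0)) msg <- c(msg, "variance fractions must be positive")
  if (anyDuplicated(object@qtlIndex)) msg <- c(msg, "QTL marker indices must be distinct")
  if (length(msg)) msg else TRUE
})
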