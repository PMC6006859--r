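#' @rdname Population-accessors
#' @name Population-accessors
#' @param x a [Population-class].
#' @param loci optional integer vector of global locus indices.
NULL

#' @rdname Population-accessors
#' @export
setMethod("nInd", "Population", function(x) ncol(x@haplotypes) %/% 2L)

#' @rdname Population-accessors
#' @export
setMethod("haplotypes", "Population", function(x) x@haplotypes)

#' @describeIn Population-accessors genotype dosage matrix (individuals x
#'   loci, counts of the reference "1" allele).
#' @export
setMethod("genotypes", "Population", function(x, loci = NULL) {
  W <- cpp_genotypes(x@haplotypes)
  rownames(W) <- x@ids
  if (!is.null(loci)) W <- W[, loci, drop = FALSE]
  W
})

#' @rdname Population-accessors
#' @export
setMethod("breedFractions", "Population", function(x) x@breedFractions)

#' @rdname Population-accessors
#' @export
setMethod("pedigree", "Population", function(x) x@pedigree)

#' @rdname Population-accessors
#' @export
setMethod("genomeMap", "Population", function(x) x@genome)

#' @rdname Population-accessors
#' @export
setMethod("popLabel", "Population", function(x) x@label)

#' @rdname Population-accessors
#' @export
setMethod("markerMap", "Population", function(x) markerMap(x@genome))

setMethod("show", "Population", function(object) {
  cat(sprintf("Population '%s': %d individuals, generation %d\n",
              object@label, nInd(object), object@generation))
  cat(sprintf("  %d loci on %d chromosomes; pedigree records: %d\n",
              nLoci(object@genome), nChromosomes(object@genome),
              nrow(object@pedigree)))
  if (ncol(object@breedFractions) > 0)
    cat("  breed fractions over:",
        paste(colnames(object@breedFractions), collapse = ", "), "\n")
})

.new_ids <- function(label, generation, n) {
  sprintf("%s_g%d_%05d", label, generation, seq_len(n))
}

.founder_pedigree <- function(ids, generation, label) {
  data.frame(id = ids, sire = NA_character_, dam = NA_character_,
             generation = generation, pop = label,
             stringsAsFactors = FALSE)
}

.merge_pedigrees <- function(...) {
  ped <- do.call(rbind, list(...))
  ped <- ped[!duplicated(ped$id), , drop = FALSE]
  ped[order(ped$generation), , drop = FALSE]
}

#' Initialize the base population
#'
#' Founders with every allele drawn independently with probability 0.5 (the
#' mutation-drift starting point of the burn-in). Breed composition is
#' undefined for the single ancestral pool (zero-column matrix).
#'
#' @param n number of individuals (>= 2).
#' @param genome a [GenomeMap-class].
#' @param label population label.
#' @return A [Population-class] of founders, generation 0.
#' @export
initBasePopulation <- function(n, genome = GenomeMap(), label = "BASE") {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("need at least 2 individuals")
  L <- nLoci(genome)
  h <- matrix(as.raw(stats::rbinom(L * 2L * n, 1L, 0.5)), nrow = L)
  ids <- .new_ids(label, 0L, n)
  new("Population", haplotypes = h, genome = genome, ids = ids,
      pedigree = .founder_pedigree(ids, 0L, label),
      breedFractions = matrix(numeric(0), nrow = n, ncol = 0),
      generation = 0L, label = label)
}

#' Simulate one meiosis
#'
#' Produces a single gamete from a pair of parental haplotypes under the
#' binomial map function: per chromosome the crossover count is
#' Binomial(maxCrossovers, L_Morgan / maxCrossovers) — so the expected number
#' of crossovers equals the map length in Morgan — with i.i.d. uniform
#' crossover positions and a fair choice of starting strand. After segment
#' copying, each locus flips allele independently with probability
#' \code{mutationRate(genome)} (reversible mutation).
#'
#' @param haps raw (or 0/1 integer) matrix, loci x 2: the parent's two
#'   haplotypes.
#' @param genome a [GenomeMap-class].
#' @return raw vector of gamete alleles (length \code{nLoci(genome)}).
#' @export
meiosis <- function(haps, genome) {
  if (is.numeric(haps) || is.integer(haps)) {
    storage.mode(haps) <- "integer"
    haps <- matrix(as.raw(haps), nrow = nrow(haps))
  }
  if (nrow(haps) != nLoci(genome) || ncol(haps) != 2)
    stop("haps must be a loci x 2 matrix matching the genome")
  g <- cpp_make_gametes(haps, 0L, .flat_positions(genome),
                        .chr_offsets(genome), chrLengths(genome),
                        genome@maxCrossovers, genome@mutationRate)
  g[, 1]
}

# one recorded generation of gametes: parents are 0-based indices
.gametes <- function(pop, parents0) {
  cpp_make_gametes(pop@haplotypes, as.integer(parents0),
                   .flat_positions(pop@genome), .chr_offsets(pop@genome),
                   chrLengths(pop@genome), pop@genome@maxCrossovers,
                   pop@genome@mutationRate)
}

.offspring_population <- function(pop, sire0, dam0, label, popB = NULL) {
  # sire0 indexes pop; dam0 indexes popB when given (cross), else pop
  dpop <- if (is.null(popB)) pop else popB
  n <- length(sire0)
  L <- nrow(pop@haplotypes)
  h <- matrix(raw(0), nrow = L, ncol = 2L * n)
  h[, seq(1L, 2L * n, by = 2L)] <- .gametes(pop, sire0)
  h[, seq(2L, 2L * n, by = 2L)] <- .gametes(dpop, dam0)
  gen <- max(pop@generation, dpop@generation) + 1L
  ids <- .new_ids(label, gen, n)
  ped_new <- data.frame(id = ids,
                        sire = pop@ids[sire0 + 1L],
                        dam = dpop@ids[dam0 + 1L],
                        generation = gen, pop = label,
                        stringsAsFactors = FALSE)
  ped <- .merge_pedigrees(pop@pedigree, dpop@pedigree, ped_new)
  bfa <- pop@breedFractions
  bfb <- dpop@breedFractions
  if (ncol(bfa) != ncol(bfb))
    stop("parental populations disagree on breed-fraction columns")
  bf <- if (ncol(bfa) == 0) matrix(numeric(0), nrow = n, ncol = 0)
        else (bfa[sire0 + 1L, , drop = FALSE] + bfb[dam0 + 1L, , drop = FALSE]) / 2
  new("Population", haplotypes = h, genome = pop@genome, ids = ids,
      pedigree = ped, breedFractions = bf, generation = gen, label = label)
}

#' Random mating
#'
#' Monoecious random union without selfing: each offspring draws two distinct
#' parents uniformly, one gamete per parent. With \code{recordPedigree =
#' FALSE} and constant population size the whole multi-generation phase runs
#' in compiled code and the resulting cohort is re-founded (its pedigree
#' starts at itself) — this is how the long neutral burn-in and breed-drift
#' phases are run, where deep pedigree is deliberately not retained.
#'
#' @param pop a [Population-class] with at least 2 individuals.
#' @param nOffspring cohort size of each new generation.
#' @param generations number of discrete generations to advance.
#' @param recordPedigree keep pedigree records (one generation at a time)?
#' @return A [Population-class] for the final generation.
#' @export
randomMate <- function(pop, nOffspring = nInd(pop), generations = 1L,
                       recordPedigree = TRUE) {
  n <- nInd(pop)
  if (n < 2) stop("need at least 2 parents")
  nOffspring <- as.integer(nOffspring)
  if (nOffspring < 1) stop("nOffspring must be positive")
  if (!recordPedigree && nOffspring == n) {
    h <- cpp_random_mate_phase(pop@haplotypes, as.integer(generations),
                               .flat_positions(pop@genome),
                               .chr_offsets(pop@genome),
                               chrLengths(pop@genome),
                               pop@genome@maxCrossovers,
                               pop@genome@mutationRate)
    gen <- pop@generation + as.integer(generations)
    ids <- .new_ids(pop@label, gen, n)
    bf <- pop@breedFractions
    if (ncol(bf) > 0) bf <- matrix(rep(colMeans(bf), each = n), nrow = n,
                                   dimnames = list(NULL, colnames(bf)))
    return(new("Population", haplotypes = h, genome = pop@genome, ids = ids,
               pedigree = .founder_pedigree(ids, gen, pop@label),
               breedFractions = bf, generation = gen, label = pop@label))
  }
  out <- pop
  for (g in seq_len(generations)) {
    m <- nInd(out)
    sire0 <- sample.int(m, nOffspring, replace = TRUE) - 1L
    dam0 <- vapply(sire0, function(s) {
      d <- s
      while (d == s) d <- sample.int(m, 1L) - 1L
      d
    }, 0L)
    out <- .offspring_population(out, sire0, dam0, out@label)
  }
  out
}

#' Found diverged breeds from the base population
#'
#' Draws independent random samples (without replacement within each sample)
#' from the base population and lets each drift for \code{generations}
#' discrete generations at constant size. Each resulting breed cohort is a
#' pedigree founder cohort carrying a unit breed-fraction vector.
#'
#' @param base burned-in base [Population-class].
#' @param nBreeds number of breeds.
#' @param sampleSize founders sampled per breed (also the drift Ne).
#' @param generations divergence generations.
#' @param labels breed labels.
#' @return Named list of [Population-class] objects.
#' @export
foundBreeds <- function(base, nBreeds = 4L, sampleSize = 100L,
                        generations = 50L, labels = LETTERS[seq_len(nBreeds)]) {
  if (sampleSize > nInd(base)) stop("sampleSize exceeds base population size")
  breeds <- vector("list", nBreeds)
  names(breeds) <- labels
  for (b in seq_len(nBreeds)) {
    take <- sample.int(nInd(base), sampleSize)
    cols <- as.vector(rbind(2L * take - 1L, 2L * take))
    h <- base@haplotypes[, cols, drop = FALSE]
    ids <- .new_ids(labels[b], base@generation, sampleSize)
    bf <- matrix(0, nrow = sampleSize, ncol = nBreeds,
                 dimnames = list(NULL, labels))
    bf[, b] <- 1
    pop <- new("Population", haplotypes = h, genome = base@genome, ids = ids,
               pedigree = .founder_pedigree(ids, base@generation, labels[b]),
               breedFractions = bf, generation = base@generation,
               label = labels[b])
    if (generations > 0)
      pop <- randomMate(pop, generations = generations, recordPedigree = FALSE)
    # drift cohort is the pedigree-founder cohort for downstream kinship
    breeds[[b]] <- pop
  }
  breeds
}

#' Half-sib expansion of a breed
#'
#' Expands a breed cohort to size \code{n} as paternal half-sib families:
#' \code{nSires} sires are drawn at random; each offspring draws its sire
#' uniformly from the sire set and its dam uniformly from the non-sire
#' individuals. Family sizes are left unequal by chance.
#'
#' @param breed a [Population-class].
#' @param n offspring cohort size.
#' @param nSires number of sires.
#' @return A [Population-class] of size \code{n}.
#' @export
expandHalfSib <- function(breed, n = 1000L, nSires = 50L) {
  m <- nInd(breed)
  if (nSires > m) stop("nSires exceeds breed size")
  if (nSires < 1 || n < 1) stop("counts must be positive")
  sires <- sample.int(m, nSires)
  dams <- setdiff(seq_len(m), sires)
  if (!length(dams)) stop("no dams left after drawing sires")
  sire0 <- sires[sample.int(nSires, n, replace = TRUE)] - 1L
  dam0 <- dams[sample.int(length(dams), n, replace = TRUE)] - 1L
  .offspring_population(breed, sire0, dam0, breed@label)
}

#' Cross two populations
#'
#' Each offspring has one parent drawn uniformly from each population; breed
#' fractions are the average of the parental fractions.
#'
#' @param popA,popB parent [Population-class] cohorts.
#' @param n number of offspring.
#' @param label label for the cross (e.g. "AB", "(AB)(CD)").
#' @return A [Population-class].
#' @export
crossPopulations <- function(popA, popB, n = 1000L,
                             label = paste0(popA@label, popB@label)) {
  if (nInd(popA) < 1 || nInd(popB) < 1) stop("empty parent population")
  if (n < 1) stop("offspring count must be positive")
  sire0 <- sample.int(nInd(popA), n, replace = TRUE) - 1L
  dam0 <- sample.int(nInd(popB), n, replace = TRUE) - 1L
  .offspring_population(popA, sire0, dam0, label, popB = popB)
}

#' Assemble the admixed sample
#'
#' Samples \code{n} individuals without replacement from the pooled cohorts,
#' carrying over haplotypes, pedigree and breed fractions.
#'
#' @param pops list of [Population-class] cohorts (same genome and breed set).
#' @param n sample size.
#' @param label label of the admixed sample.
#' @return A [Population-class].
#' @export
buildAdmixed <- function(pops, n = 1000L, label = "ADMX") {
  sizes <- vapply(pops, nInd, 1L)
  total <- sum(sizes)
  if (n > total) stop("n exceeds pooled population size")
  L <- nrow(pops[[1]]@haplotypes)
  h <- do.call(cbind, lapply(pops, function(p) p@haplotypes))
  ids <- unlist(lapply(pops, function(p) p@ids), use.names = FALSE)
  bf <- do.call(rbind, lapply(pops, breedFractions))
  src <- rep(vapply(pops, popLabel, ""), sizes)
  take <- sort(sample.int(total, n))
  cols <- as.vector(rbind(2L * take - 1L, 2L * take))
  ped <- do.call(.merge_pedigrees, lapply(pops, pedigree))
  gen <- max(vapply(pops, function(p) p@generation, 1L))
  pop <- new("Population", haplotypes = h[, cols, drop = FALSE],
             genome = pops[[1]]@genome, ids = ids[take],
             pedigree = ped,
             breedFractions = bf[take, , drop = FALSE],
             generation = gen, label = label)
  pop
}

#' Select the association marker panel
#'
#' Picks, per chromosome, \code{perChromosome} segregating loci (0 < freq < 1
#' in the cohort) as evenly spaced as possible: the segregating locus nearest
#' each of \code{perChromosome} equally spaced target positions is chosen
#' (ties resolved toward the lower index; a locus already taken falls through
#' to the next nearest).
#'
#' @param pop cohort whose allele frequencies define "segregating".
#' @param perChromosome panel size per chromosome.
#' @return Sorted integer vector of global locus indices.
#' @export
selectMarkerPanel <- function(pop, perChromosome = 1000L) {
  freq <- alleleFreqs(pop)
  map <- markerMap(pop@genome)
  seg <- freq > 0 & freq < 1
  out <- integer(0)
  for (c in seq_len(nChromosomes(pop@genome))) {
    on_chr <- which(map$chr == c & seg)
    if (length(on_chr) < perChromosome)
      stop(sprintf("chromosome %d has only %d segregating loci (need %d)",
                   c, length(on_chr), perChromosome))
    pos <- map$pos[on_chr]
    len <- chrLengths(pop@genome)[c]
    targets <- (seq_len(perChromosome) - 0.5) * len / perChromosome
    used <- logical(length(on_chr))
    pick <- integer(perChromosome)
    for (t in seq_along(targets)) {
      ord <- order(abs(pos - targets[t]), seq_along(pos))
      j <- ord[!used[ord]][1]
      used[j] <- TRUE
      pick[t] <- on_chr[j]
    }
    out <- c(out, sort(pick))
  }
  out
}

#' Pedigree-based additive relationship matrix
#'
#' Tabular-method numerator relationship matrix, restricted to
#' \code{subjectIds}. The pedigree is pruned to the subjects and their
#' recorded ancestors; pedigree founders are treated as unrelated and
#' non-inbred.
#'
#' @param ped pedigree data.frame (\code{id}, \code{sire}, \code{dam},
#'   \code{generation}) sorted so parents precede offspring, or a
#'   [Population-class].
#' @param subjectIds ids to restrict the matrix to.
#' @return numeric matrix with \code{subjectIds} dimnames.
#' @export
pedigreeA <- function(ped, subjectIds) {
  if (is(ped, "Population")) ped <- pedigree(ped)
  if (!all(subjectIds %in% ped$id)) stop("unknown subject id(s)")
  # prune to ancestors of the subjects
  keep <- character(0)
  frontier <- unique(subjectIds)
  while (length(frontier)) {
    keep <- c(keep, frontier)
    rows <- ped[match(frontier, ped$id), , drop = FALSE]
    frontier <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), keep)
  }
  ped <- ped[ped$id %in% keep, , drop = FALSE]
  ped <- ped[order(ped$generation), , drop = FALSE]
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  s <- idx[ped$sire]
  d <- idx[ped$dam]
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  self <- seq_along(s)
  if (any(s >= self & s > 0) || any(d >= self & d > 0))
    stop("pedigree is cyclic or not sortable with parents before offspring")
  A <- cpp_tabular_A(as.integer(s), as.integer(d))
  dimnames(A) <- list(ped$id, ped$id)
  A[subjectIds, subjectIds]
}
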