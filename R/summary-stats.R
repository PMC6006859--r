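#' Allele frequencies
#'
#' Frequency of the reference "1" allele per locus in a cohort.
#'
#' @param pop a [Population-class].
#' @param loci optional global locus indices.
#' @return numeric vector of frequencies.
#' @export
alleleFreqs <- function(pop, loci = NULL) {
  W <- genotypes(pop, loci)
  colMeans(W) / 2
}

#' Linkage disequilibrium (r-squared) by map distance
#'
#' Mean squared genotype-count correlation between marker pairs whose
#' within-chromosome distance falls within \code{tol} of each target distance.
#' Monomorphic markers are excluded (their correlation is undefined).
#'
#' @param pop a [Population-class].
#' @param panel global locus indices of the marker panel.
#' @param distances target distances in cM.
#' @param tol half-width of the closed distance window; defaults to half the
#'   median panel spacing.
#' @return data.frame with columns \code{distance}, \code{mean_r2},
#'   \code{n_pairs}.
#' @export
ldByDistance <- function(pop, panel, distances = c(1, 2), tol = NULL) {
  if (!length(panel)) stop("empty panel")
  map <- markerMap(pop@genome)[panel, , drop = FALSE]
  W <- genotypes(pop, panel)
  sds <- apply(W, 2, stats::sd)
  poly <- sds > 0
  if (is.null(tol)) {
    sp <- unlist(tapply(map$pos, map$chr, function(p) diff(sort(p))))
    tol <- stats::median(sp) / 2
  }
  Wc <- scale(W, center = TRUE, scale = FALSE)
  n <- nrow(W)
  out <- data.frame(distance = distances, mean_r2 = NA_real_, n_pairs = 0L)
  for (k in seq_along(distances)) {
    d <- distances[k]
    r2 <- numeric(0)
    for (c in unique(map$chr)) {
      on <- which(map$chr == c & poly)
      if (length(on) < 2) next
      pos <- map$pos[on]
      # two-pointer scan over ordered positions
      j0 <- 1L
      for (i in seq_along(on)) {
        lo <- pos[i] + d - tol
        hi <- pos[i] + d + tol
        while (j0 <= length(on) && pos[j0] < lo) j0 <- j0 + 1L
        j <- j0
        while (j <= length(on) && pos[j] <= hi) {
          if (j > i) {
            a <- Wc[, on[i]]
            b <- Wc[, on[j]]
            r <- sum(a * b) / ((n - 1) * sds[on[i]] * sds[on[j]])
            r2 <- c(r2, r * r)
          }
          j <- j + 1L
        }
      }
    }
    out$mean_r2[k] <- if (length(r2)) mean(r2) else NA_real_
    out$n_pairs[k] <- length(r2)
  }
  out
}

#' Pairwise Wright's F_ST between populations
#'
#' Hudson-style moment estimator computed as a ratio of sums over loci: the
#' numerator is the squared allele-frequency difference corrected for
#' within-population sampling, the denominator the between-population
#' heterozygosity \eqn{p_1(1-p_2) + p_2(1-p_1)}. Under pure drift from a
#' common base its expectation is \eqn{F = 1-(1-1/(2N_e))^t}, the quantity the
#' simulated breed divergence is designed to produce.
#'
#' @param pops list of [Population-class] cohorts.
#' @param loci optional global locus indices (defaults to all loci
#'   segregating in the pooled sample).
#' @return symmetric matrix of pairwise F_ST values.
#' @export
fstPairwise <- function(pops, loci = NULL) {
  k <- length(pops)
  if (k < 2) stop("need at least two populations")
  freqs <- lapply(pops, alleleFreqs, loci = loci)
  ns <- vapply(pops, function(p) 2 * nInd(p), 1)
  if (is.null(loci)) {
    pool <- Reduce(`+`, Map(`*`, freqs, ns)) / sum(ns)
    keep <- pool > 0 & pool < 1
    freqs <- lapply(freqs, function(f) f[keep])
  }
  out <- matrix(0, k, k, dimnames = list(names(pops), names(pops)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p1 <- freqs[[i]]; p2 <- freqs[[j]]
      num <- (p1 - p2)^2 -
        p1 * (1 - p1) / (ns[i] - 1) - p2 * (1 - p2) / (ns[j] - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      ok <- den > 0
      out[i, j] <- out[j, i] <- sum(num[ok]) / sum(den[ok])
    }
  }
  out
}

#' Principal components of the genotype matrix
#'
#' Projections of the column-centered genotype matrix onto its leading
#' eigenvectors, with the percentage of variance explained per component.
#'
#' @param pop a [Population-class].
#' @param panel global locus indices of the markers to use.
#' @param nComp number of components to return.
#' @return list with \code{scores} (individuals x nComp) and
#'   \code{varExplained} (percentages).
#' @export
pcaScores <- function(pop, panel, nComp = 2L) {
  W <- genotypes(pop, panel)
  keep <- apply(W, 2, stats::sd) > 0
  pc <- stats::prcomp(W[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  nComp <- min(nComp, ncol(pc$x))
  list(scores = pc$x[, seq_len(nComp), drop = FALSE],
       varExplained = 100 * pc$sdev[seq_len(nComp)]^2 / sum(pc$sdev^2))
}

#' Cohort summary statistics
#'
#' Convenience wrapper collecting allele frequencies, LD decay, PCA scores
#' and (when \code{groups} is supplied) pairwise F_ST between the groups of a
#' cohort split by origin population.
#'
#' @param pop a [Population-class].
#' @param panel marker panel (global locus indices).
#' @param distances cM distances for [ldByDistance()].
#' @param groups optional factor/character vector (length \code{nInd(pop)})
#'   splitting the cohort into sub-populations for F_ST.
#' @param nComp PCA components.
#' @return list with elements \code{alleleFreqs}, \code{ld}, \code{pca}, and
#'   optionally \code{fst}.
#' @export
summaryStats <- function(pop, panel, distances = c(1, 2), groups = NULL,
                         nComp = 2L) {
  out <- list(
    alleleFreqs = alleleFreqs(pop, panel),
    ld = ldByDistance(pop, panel, distances),
    pca = pcaScores(pop, panel, nComp)
  )
  if (!is.null(groups)) {
    groups <- as.character(groups)
    stopifnot(length(groups) == nInd(pop))
    subpops <- lapply(split(seq_len(nInd(pop)), groups), function(ix)
      .subset_population(pop, ix))
    out$fst <- fstPairwise(subpops, loci = panel)
  }
  out
}

# internal: cohort subset keeping pedigree/fractions aligned
.subset_population <- function(pop, ix) {
  cols <- as.vector(rbind(2L * ix - 1L, 2L * ix))
  bf <- pop@breedFractions
  if (ncol(bf) > 0) bf <- bf[ix, , drop = FALSE]
  else bf <- matrix(numeric(0), nrow = length(ix), ncol = 0)
  new("Population", haplotypes = pop@haplotypes[, cols, drop = FALSE],
      genome = pop@genome, ids = pop@ids[ix], pedigree = pop@pedigree,
      breedFractions = bf, generation = pop@generation, label = pop@label)
}
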