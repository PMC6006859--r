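#' Default QTL target positions and variance weights
#'
#' Fifteen QTL on chromosomes 1 to 3 (none on chromosomes 4 to 6): ten
#' explaining 1 percent of the trait variance each, four explaining 3 percent,
#' and one explaining 6 percent. Positions are within-chromosome cM
#' (genome-cumulative coordinates 100-200 on chromosome 2 and 200-300 on
#' chromosome 3 are converted).
#'
#' @return data.frame with columns \code{chr}, \code{pos}, \code{varFraction}.
#' @export
qtlTargets <- function() {
  data.frame(
    chr = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 1L, 2L, 2L, 3L, 1L),
    pos = c(60, 61, 95, 21, 25, 60, 5, 15, 25, 40, 75, 20, 80, 70, 15),
    varFraction = c(rep(0.01, 10), rep(0.03, 4), 0.06)
  )
}

#' @rdname QTLArchitecture-accessors
#' @param x a [QTLArchitecture-class].
#' @export
setMethod("qtlIndex", "QTLArchitecture", function(x) x@qtlIndex)

#' @rdname QTLArchitecture-accessors
#' @export
setMethod("qtlEffects", "QTLArchitecture", function(x) x@effects)

setMethod("show", "QTLArchitecture", function(object) {
  cat(sprintf("QTLArchitecture: %d QTL on chromosomes %s (target h2 = %.2f)\n",
              length(object@qtlIndex),
              paste(sort(unique(object@chr)), collapse = ","), object@h2))
  if (!all(is.na(object@effects)))
    cat("  |effects| range:",
        paste(format(range(abs(object@effects)), digits = 3), collapse = " - "), "\n")
})

#' Select QTL markers near target positions
#'
#' For each target, the panel marker on the target chromosome that is nearest
#' to the target position among those segregating with MAF >
#' \code{mafMin} in the cohort is chosen (ties toward the lower index; a
#' marker already assigned to a previous QTL falls through to the next
#' nearest). The chosen markers must subsequently be removed from the
#' association panel (see [dropQtlFromPanel()]).
#'
#' @param pop training cohort (defines frequencies).
#' @param panel marker panel (global locus indices).
#' @param targets data.frame as returned by [qtlTargets()].
#' @param mafMin minimum minor allele frequency for a QTL marker.
#' @param h2 target heritability carried on the architecture.
#' @return A [QTLArchitecture-class] with effects unset (NA).
#' @export
selectQtl <- function(pop, panel, targets = qtlTargets(), mafMin = 0.02,
                      h2 = 0.30) {
  map <- markerMap(pop@genome)
  len <- chrLengths(pop@genome)
  if (any(targets$pos < 0 | targets$pos > len[targets$chr]))
    stop("QTL target position outside chromosome bounds")
  freq <- alleleFreqs(pop, panel)
  maf <- pmin(freq, 1 - freq)
  used <- logical(length(panel))
  idx <- integer(nrow(targets))
  for (t in seq_len(nrow(targets))) {
    cand <- which(map$chr[panel] == targets$chr[t] & maf > mafMin & !used)
    if (!length(cand))
      stop(sprintf("no qualifying QTL marker on chromosome %d", targets$chr[t]))
    ord <- cand[order(abs(map$pos[panel[cand]] - targets$pos[t]), cand)]
    used[ord[1]] <- TRUE
    idx[t] <- panel[ord[1]]
  }
  new("QTLArchitecture", qtlIndex = idx, chr = as.integer(targets$chr),
      pos = map$pos[idx], varFraction = targets$varFraction,
      effects = rep(NA_real_, length(idx)), h2 = h2)
}

#' Remove QTL markers from an association panel
#'
#' @param panel integer vector of global locus indices.
#' @param arch a [QTLArchitecture-class].
#' @return the panel without the QTL markers.
#' @export
dropQtlFromPanel <- function(panel, arch) setdiff(panel, arch@qtlIndex)

#' Standardize QTL allele-substitution effects
#'
#' Sets \eqn{|a_k| = \sqrt{v'_k \sigma^2_g} / sd(w_k)}, where \eqn{sd(w_k)} is
#' the empirical genotype-count standard deviation of QTL k in the reference
#' (admixed) cohort, \eqn{v'_k} the variance fractions renormalized to sum to
#' one, and \eqn{\sigma^2_g = h^2/(1-h^2)} times the residual variance (3/7
#' for h2 = 0.30 with unit residual). Signs are assigned negative or positive
#' with equal probability. By construction each QTL's realized variance share
#' in the reference cohort (ignoring LD between QTL) is exactly \eqn{v'_k}.
#'
#' @param pop reference cohort in which effects are standardized.
#' @param arch a [QTLArchitecture-class] from [selectQtl()].
#' @param residVar residual variance of the phenotype (default 1).
#' @return the architecture with \code{effects} filled in.
#' @export
standardizeEffects <- function(pop, arch, residVar = 1) {
  W <- genotypes(pop, arch@qtlIndex)
  sdw <- apply(W, 2, stats::sd)
  if (any(sdw == 0)) stop("QTL with zero genotype variance in the cohort")
  sigma2g <- arch@h2 / (1 - arch@h2) * residVar
  vprime <- arch@varFraction / sum(arch@varFraction)
  a <- sqrt(vprime * sigma2g) / sdw
  signs <- ifelse(stats::runif(length(a)) < 0.5, -1, 1)
  arch@effects <- a * signs
  validObject(arch)
  arch
}

#' Simulate true breeding values and phenotypes
#'
#' \eqn{tbv_i = \sum_k a_k w_{ik}} over the QTL, and \eqn{y_i = tbv_i +
#' N(0, residSd^2)}; purely additive.
#'
#' @param pop cohort to phenotype.
#' @param arch a [QTLArchitecture-class] with effects assigned.
#' @param residSd residual standard deviation (default 1: the phenotype adds
#'   a standard-normal deviate to the true breeding value).
#' @return data.frame with columns \code{id}, \code{tbv}, \code{y}; attributes
#'   \code{target_h2} and \code{residual_sd}.
#' @export
simulatePhenotypes <- function(pop, arch, residSd = 1) {
  if (anyNA(arch@effects)) stop("QTL effects not assigned; run standardizeEffects()")
  W <- genotypes(pop, arch@qtlIndex)
  tbv <- as.vector(W %*% arch@effects)
  y <- tbv + stats::rnorm(nInd(pop), 0, residSd)
  out <- data.frame(id = pop@ids, tbv = tbv, y = y, stringsAsFactors = FALSE)
  attr(out, "target_h2") <- arch@h2
  attr(out, "residual_sd") <- residSd
  out
}
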