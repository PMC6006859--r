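#' Null-chromosome (NCHR) empirical significance threshold
#'
#' Divides each null chromosome into non-overlapping bins of
#' \code{binMarkers} consecutive panel markers, records the per-bin extreme
#' statistic (minimum p-value, or maximum PIP for the Bayesian scale) for
#' every replicate of a dataset, pools all bins and replicates, and returns
#' the \code{level} quantile (\code{1 - level} for PIP) using type-7 linear
#' interpolation. Thresholds are dataset-specific and are never shared across
#' datasets. Only complete bins are used.
#'
#' @param results one scan data.frame, or a list of them (one per replicate);
#'   each needs columns \code{chr}, \code{pos} and \code{p} (or \code{pip}).
#' @param nullChr chromosomes simulated without QTL.
#' @param binMarkers markers per bin (40 at the default panel density of 10
#'   markers/cM, i.e. +/- 2 cM).
#' @param level family-wise construction level.
#' @param scale \code{"p"} or \code{"pip"}.
#' @return list of class \code{"ThresholdSet"}: \code{method}, \code{scale},
#'   \code{level}, \code{value}, \code{binMarkers}, \code{nBins}.
#' @export
nchrThreshold <- function(results, nullChr = 4:6, binMarkers = 40L,
                          level = 0.05, scale = c("p", "pip")) {
  scale <- match.arg(scale)
  if (is.data.frame(results)) results <- list(results)
  stat_col <- if (scale == "p") "p" else "pip"
  pooled <- numeric(0)
  for (res in results) {
    if (!all(c("chr", "pos", stat_col) %in% names(res)))
      stop("scan results need columns chr, pos, ", stat_col)
    for (c in nullChr) {
      on <- res[res$chr == c & !is.na(res[[stat_col]]), , drop = FALSE]
      on <- on[order(on$pos), , drop = FALSE]
      nb <- nrow(on) %/% binMarkers
      if (nb == 0) next
      idx <- rep(seq_len(nb), each = binMarkers)
      v <- on[[stat_col]][seq_len(nb * binMarkers)]
      ext <- if (scale == "p") tapply(v, idx, min) else tapply(v, idx, max)
      pooled <- c(pooled, as.numeric(ext))
    }
  }
  if (!length(pooled)) stop("no complete null-chromosome bins")
  q <- if (scale == "p") level else 1 - level
  out <- list(method = "NCHR", scale = scale, level = level,
              value = unname(stats::quantile(pooled, q, type = 7)),
              binMarkers = as.integer(binMarkers), nBins = length(pooled))
  class(out) <- "ThresholdSet"
  out
}

#' Sliding-window effective number of tests (Meff)
#'
#' Monte-Carlo estimate of the effective number of independent tests in a
#' marker panel. Genome-wide vectors of test statistics are drawn from the
#' locally correlated Gaussian implied by the genotype-count correlations: the
#' statistic at each marker is generated conditionally on the previous
#' \code{windowMarkers - 1} markers of the same chromosome (a sliding-window
#' banded approximation of the full multivariate normal). The empirical
#' \code{1 - alpha} quantile of the per-cycle genome-wide maximum |Z| defines
#' the per-test two-sided level alpha*, and Meff = alpha / alpha*. Singular
#' window correlation matrices are ridge-stabilized.
#'
#' @param W genotype dosage matrix over the panel (monomorphic columns are
#'   dropped with a warning).
#' @param map per-marker data.frame with \code{chr} and \code{pos} (ordered
#'   within chromosome).
#' @param windowMarkers sliding window size in markers.
#' @param nMc Monte-Carlo cycles.
#' @param seed optional RNG seed.
#' @param alpha family-wise level.
#' @return list with \code{meff}, \code{alphaStar}, \code{maxZquantile},
#'   \code{nMc}, \code{nMarkers}.
#' @export
slideMeff <- function(W, map, windowMarkers = 40L, nMc = 100000L, seed = NULL,
                      alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(map) == ncol(W))
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " monomorphic marker(s) dropped from Meff panel")
    W <- W[, sds > 0, drop = FALSE]
    map <- map[sds > 0, , drop = FALSE]
  }
  p <- ncol(W)
  if (windowMarkers > p) stop("window exceeds panel size")
  wlag <- windowMarkers - 1L
  B <- matrix(0, max(wlag, 1L), p)
  mlag <- integer(p)
  csd <- numeric(p)
  col <- 0L
  for (c in unique(map$chr)) {
    on <- which(map$chr == c)
    on <- on[order(map$pos[on])]
    R <- stats::cor(W[, on, drop = FALSE])
    for (j in seq_along(on)) {
      col <- col + 1L
      m <- min(wlag, j - 1L)
      mlag[col] <- m
      if (m == 0) { csd[col] <- 1; next }
      idx <- seq(j - 1L, j - m)  # lag order 1..m
      Sg <- R[idx, idx, drop = FALSE]
      rho <- R[idx, j]
      b <- NULL
      ridge <- 0
      repeat {
        b <- tryCatch(solve(Sg + diag(ridge, m), rho),
                      error = function(e) NULL)
        if (!is.null(b)) {
          cv <- 1 - sum(b * rho)
          if (cv > -1e-8) break
        }
        ridge <- if (ridge == 0) 1e-8 else ridge * 100
        if (ridge > 1) stop("window correlation could not be stabilized")
      }
      B[seq_len(m), col] <- b
      csd[col] <- sqrt(max(1 - sum(b * rho), 0))
    }
  }
  mx <- cpp_slide_max(B, mlag, csd, as.integer(nMc))
  t <- unname(stats::quantile(mx, 1 - alpha, type = 7))
  alphaStar <- 2 * stats::pnorm(-t)
  meff <- min(max(alpha / alphaStar, 1), p)
  list(meff = meff, alphaStar = alphaStar, maxZquantile = t,
       nMc = as.integer(nMc), nMarkers = p)
}

#' Bonferroni threshold from an effective number of tests
#'
#' @param meff effective number of tests (>= 1).
#' @param alpha family-wise level.
#' @return list of class \code{"ThresholdSet"} with \code{value} =
#'   \code{alpha / meff}.
#' @export
bonferroniThreshold <- function(meff, alpha = 0.05) {
  if (is.list(meff)) meff <- meff$meff
  if (meff < 1) stop("meff must be >= 1")
  out <- list(method = "SLIDE", scale = "p", level = alpha,
              value = alpha / meff, meff = meff)
  class(out) <- "ThresholdSet"
  out
}

#' @export
print.ThresholdSet <- function(x, ...) {
  cat(sprintf("%s threshold (%s scale, level %.2f): %.4g\n",
              x$method, x$scale, x$level, x$value))
  invisible(x)
}

#' Quantile-quantile plot data and genomic inflation factor
#'
#' Observed -log10 p order statistics against the uniform expectation
#' \code{-log10((i - 0.5)/m)}, plus the genomic inflation factor
#' \code{lambda = median(chi2) / 0.4549} of the implied 1-df chi-square
#' statistics. Zero p-values are clipped to the smallest positive double with
#' a warning.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with \code{data} (data.frame \code{expected},
#'   \code{observed}) and \code{lambda}.
#' @export
qqData <- function(p) {
  p <- p[!is.na(p)]
  if (any(p <= 0)) {
    warning("zero p-values clipped")
    p[p <= 0] <- .Machine$double.xmin
  }
  if (any(p > 1)) stop("p-values must be in (0, 1]")
  m <- length(p)
  sp <- sort(p)
  lambda <- stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  list(data = data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                         observed = -log10(sp)),
       lambda = lambda)
}
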