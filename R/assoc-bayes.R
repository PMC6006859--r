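#' Deterministic BayesCpi prior hyperparameters
#'
#' Sets the scale of the scaled-inverse-chi-square prior on the common marker
#' effect variance so that its prior mean equals the assumed genetic variance
#' divided by the expected number of QTL times the panel's mean
#' heterozygosity-variance term \eqn{\overline{2pq}}; the residual scale is
#' set analogously from the assumed residual variance. The prior mean of a
#' scaled-inverse-chi-square(\eqn{\nu}, \eqn{S^2}) is \eqn{\nu S^2/(\nu-2)},
#' so \eqn{\nu > 2} is required.
#'
#' @param geneticVariance assumed total additive genetic variance.
#' @param expectedNQtl expected number of markers with non-zero effect.
#' @param alleleFreqs panel allele frequencies, used for the mean 2pq term.
#' @param nuAlpha,nuE prior degrees of freedom (defaults 4.2 and 4).
#' @param residualVariance assumed residual variance.
#' @return list of class \code{"BayesCPriors"} with \code{S2a}, \code{nuA},
#'   \code{S2e}, \code{nuE} and the implied prior means.
#' @export
deriveHyperparameters <- function(geneticVariance, expectedNQtl, alleleFreqs,
                                  nuAlpha = 4.2, nuE = 4,
                                  residualVariance = 1) {
  if (geneticVariance <= 0) stop("geneticVariance must be positive")
  if (nuAlpha <= 2 || nuE <= 2)
    stop("prior degrees of freedom must exceed 2 for a finite prior mean")
  mean2pq <- mean(2 * alleleFreqs * (1 - alleleFreqs))
  if (mean2pq <= 0) stop("zero mean heterozygosity")
  meanS2a <- geneticVariance / (expectedNQtl * mean2pq)
  out <- list(S2a = meanS2a * (nuAlpha - 2) / nuAlpha, nuA = nuAlpha,
              S2e = residualVariance * (nuE - 2) / nuE, nuE = nuE,
              priorMeanSigma2a = meanS2a,
              priorMeanSigma2e = residualVariance)
  class(out) <- "BayesCPriors"
  out
}

#' BayesCpi Gibbs sampler
#'
#' Bayesian multiple regression with stochastic search variable selection:
#' \code{y = 1 mu [+ X beta] + sum_k gamma_k w_k alpha_k + e}. Marker effects
#' share a common variance with a scaled-inverse-chi-square prior, the
#' exclusion probability pi has a uniform prior (Beta full conditional), fixed
#' covariates get flat priors, and genotype columns enter raw (0/1/2). Per
#' sweep, each marker's indicator is sampled from the marginal likelihood
#' ratio with the effect integrated out, then the effect from its normal full
#' conditional; the residual vector is updated incrementally. The posterior
#' inclusion probability (PIP) of a marker is the mean of its post-burn-in
#' indicator draws.
#'
#' @param y phenotype vector.
#' @param W genotype dosage matrix (individuals x markers).
#' @param bc optional breed-fraction matrix added as fixed covariates (one
#'   column dropped).
#' @param priors a \code{"BayesCPriors"} list from [deriveHyperparameters()].
#' @param chainLength,burnIn MCMC chain length and burn-in (samples, not
#'   thinned).
#' @param seed optional RNG seed set before sampling.
#' @param piInit initial exclusion probability.
#' @param updateMu,updatePi,updateSigma2a,updateSigma2e update flags; fixing a
#'   block (e.g. the variances) keeps it at its initial value, which is how
#'   the sampler is checked against conjugate closed forms.
#' @param sigma2aInit,sigma2eInit initial (or fixed) variances; default to the
#'   prior means.
#' @param thin store every \code{thin}-th monitored sample (PIPs always use
#'   every post-burn-in sweep).
#' @param map optional per-marker map data.frame.
#' @param drop breed column dropped from the design.
#' @return list of class \code{"BayesCResult"}: \code{markers} (data.frame
#'   with \code{marker}, \code{pip}, \code{alphaMean}, model tag),
#'   \code{trace} (monitored samples of sigma2_e, sigma2_a, pi, model size),
#'   \code{diagnostics} (from [chainDiagnostics()]), and \code{settings}.
#' @export
gibbsBayesCpi <- function(y, W, bc = NULL, priors, chainLength = 100000L,
                          burnIn = 10000L, seed = NULL, piInit = 0.5,
                          updateMu = TRUE, updatePi = TRUE,
                          updateSigma2a = TRUE, updateSigma2e = TRUE,
                          sigma2aInit = priors$priorMeanSigma2a,
                          sigma2eInit = priors$priorMeanSigma2e,
                          thin = max(1L, chainLength %/% 20000L),
                          map = NULL, drop = if (is.null(bc)) NULL else ncol(bc)) {
  if (!is.null(seed)) set.seed(seed)
  X <- if (is.null(bc)) matrix(0, length(y), 0) else bcDesign(bc, drop)
  storage.mode(W) <- "double"
  storage.mode(X) <- "double"
  fit <- cpp_bayescpi(y, W, X, priors$S2a, priors$nuA, priors$S2e, priors$nuE,
                      as.integer(chainLength), as.integer(burnIn),
                      piInit, sigma2aInit, sigma2eInit,
                      updateMu, updatePi, updateSigma2a, updateSigma2e,
                      as.integer(thin))
  model <- if (is.null(bc)) "BMR" else "BMR_BC"
  markers <- data.frame(marker = seq_len(ncol(W)), pip = fit$pip,
                        alphaMean = fit$alpha_mean, model = model,
                        stringsAsFactors = FALSE)
  markers <- .attach_map(markers, map)
  tr <- fit$trace[seq_len(fit$n_stored), , drop = FALSE]
  colnames(tr) <- c("sigma2_e", "sigma2_a", "pi", "model_size")
  post <- tr[seq_len(nrow(tr)) * thin > burnIn, , drop = FALSE]
  diags <- tryCatch(chainDiagnostics(post), error = function(e) NULL)
  out <- list(markers = markers, trace = tr, diagnostics = diags,
              settings = list(chainLength = chainLength, burnIn = burnIn,
                              thin = thin, priors = priors, model = model,
                              seed = seed))
  class(out) <- "BayesCResult"
  out
}

#' @export
print.BayesCResult <- function(x, ...) {
  cat(sprintf("BayesCpi result (%s): %d markers, chain %d (burn-in %d)\n",
              x$settings$model, nrow(x$markers), x$settings$chainLength,
              x$settings$burnIn))
  cat(sprintf("  mean model size (sum PIP): %.2f; top PIP: %.3f\n",
              sum(x$markers$pip), max(x$markers$pip)))
  invisible(x)
}

# autoregressive estimate of the spectral density at frequency zero,
# the long-run variance used by ESS and the Geweke diagnostic
.spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(NA_real_)
  fit <- tryCatch(stats::ar(x, aic = TRUE), error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' MCMC chain diagnostics
#'
#' Effective sample size (autoregressive spectral estimator) and Geweke z
#' score (first 10 percent vs last 50 percent of the chain) for each monitored
#' scalar. A constant chain is flagged degenerate (NA diagnostics).
#'
#' @param samples matrix or data.frame of post-burn-in samples, one column per
#'   monitored scalar.
#' @return data.frame with \code{variable}, \code{n}, \code{ess},
#'   \code{geweke_z}, \code{degenerate}.
#' @export
chainDiagnostics <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 10) stop("chain too short for diagnostics")
  do.call(rbind, lapply(colnames(samples), function(nm) {
    x <- samples[, nm]
    n <- length(x)
    if (stats::var(x) == 0)
      return(data.frame(variable = nm, n = n, ess = NA_real_,
                        geweke_z = NA_real_, degenerate = TRUE))
    s0 <- .spectrum0_ar(x)
    ess <- min(n, n * stats::var(x) / s0)
    x1 <- x[seq_len(floor(0.1 * n))]
    x2 <- x[seq(floor(0.5 * n) + 1, n)]
    se2 <- .spectrum0_ar(x1) / length(x1) + .spectrum0_ar(x2) / length(x2)
    z <- (mean(x1) - mean(x2)) / sqrt(se2)
    data.frame(variable = nm, n = n, ess = ess, geweke_z = z,
               degenerate = FALSE)
  }))
}
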