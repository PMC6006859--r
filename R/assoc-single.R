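#' Breed-composition design columns
#'
#' Builds the fixed-effect covariate block for breed composition: all breed
#' ancestry-fraction columns except one (the last by default) are kept, so the
#' design [intercept | BC] has full column rank (the fractions sum to 1).
#'
#' @param bc individuals x breeds matrix of ancestry fractions (rows sum to 1).
#' @param drop name or index of the breed column to drop.
#' @return matrix with q - 1 columns.
#' @export
bcDesign <- function(bc, drop = ncol(bc)) {
  bc <- as.matrix(bc)
  if (any(abs(rowSums(bc) - 1) > 1e-8)) stop("breed-fraction rows must sum to 1")
  # a single-breed cohort carries no BC information: empty covariate block
  if (ncol(bc) < 2) return(bc[, 0, drop = FALSE])
  bc[, -match_drop(bc, drop), drop = FALSE]
}

match_drop <- function(bc, drop) {
  if (is.character(drop)) match(drop, colnames(bc)) else as.integer(drop)
}

# shared OLS scan machinery: y and each marker column are residualized on the
# covariate block C (which always includes the intercept), then tested by a
# per-marker Wald statistic (beta/se)^2 on chi-square(1), with the residual
# variance estimated from that marker's fit.
.ols_scan <- function(y, W, C, model, map = NULL) {
  n <- length(y)
  stopifnot(nrow(W) == n, nrow(C) == n)
  qr_c <- qr(C)
  if (qr_c$rank < ncol(C)) {
    bad <- colnames(C)[qr_c$pivot[seq(qr_c$rank + 1, ncol(C))]]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  yr <- qr.resid(qr_c, y)
  Wr <- qr.resid(qr_c, W)
  sxx <- colSums(Wr^2)
  syy <- sum(yr^2)
  testable <- sxx > n * .Machine$double.eps
  beta <- se <- wald <- p <- rep(NA_real_, ncol(W))
  sxy <- as.vector(crossprod(Wr, yr))
  df <- n - ncol(C) - 1
  b <- sxy[testable] / sxx[testable]
  rss <- pmax(syy - b^2 * sxx[testable], 0)
  s2 <- rss / df
  se_t <- sqrt(s2 / sxx[testable])
  beta[testable] <- b
  se[testable] <- se_t
  wald[testable] <- (b / se_t)^2
  p[testable] <- stats::pchisq(wald[testable], df = 1, lower.tail = FALSE)
  res <- data.frame(marker = seq_len(ncol(W)), beta = beta, se = se,
                    wald = wald, p = p, testable = testable, model = model,
                    stringsAsFactors = FALSE)
  .attach_map(res, map)
}

.attach_map <- function(res, map) {
  if (!is.null(map)) {
    res$chr <- map$chr
    res$pos <- map$pos
    if (!is.null(map$locus)) res$marker <- map$locus
  }
  res
}

#' Single-marker simple regression scan
#'
#' Ordinary least squares of the phenotype on each marker's genotype dosage,
#' one marker at a time (\code{y = 1 mu + w a + e}); the Wald statistic
#' \code{(a/SE)^2} is referred to chi-square with 1 df. Monomorphic markers
#' are reported untestable rather than raising an error.
#'
#' @param y phenotype vector.
#' @param W genotype dosage matrix (individuals x markers, 0/1/2).
#' @param map optional data.frame with per-marker \code{locus}, \code{chr},
#'   \code{pos} (one row per column of W).
#' @return data.frame with columns \code{marker}, \code{beta}, \code{se},
#'   \code{wald}, \code{p}, \code{testable}, \code{model} (and map columns).
#' @export
smaScan <- function(y, W, map = NULL) {
  .ols_scan(y, W, matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
            "SMA", map)
}

#' Single-marker regression with breed composition
#'
#' As [smaScan()] with the breed-composition covariates added to the fixed
#' part (\code{y = 1 mu + X beta + w a + e}); one breed column is dropped for
#' identifiability.
#'
#' @inheritParams smaScan
#' @param bc individuals x breeds ancestry-fraction matrix.
#' @param drop breed column dropped from the design.
#' @return scan data.frame (model tag "SMA_BC").
#' @export
smaBcScan <- function(y, W, bc, map = NULL, drop = ncol(bc)) {
  X <- bcDesign(bc, drop)
  C <- cbind(`(Intercept)` = 1, X)
  .ols_scan(y, W, C, "SMA_BC", map)
}

#' Wald test of the breed-composition effect
#'
#' Joint Wald test of the BC coefficients in the no-marker model, under OLS
#' or (when \code{A} and variance components are supplied) under GLS with
#' \code{V = A sigma2_u + I sigma2_e}.
#'
#' @param y phenotype vector.
#' @param bc breed-fraction matrix.
#' @param A optional additive relationship matrix for the GLS version.
#' @param vc optional list with \code{sigma2_u}, \code{sigma2_e} (estimated
#'   via [remlVarianceComponents()] when missing).
#' @param drop breed column dropped from the design.
#' @return list with \code{wald}, \code{df}, \code{p}.
#' @export
bcEffectTest <- function(y, bc, A = NULL, vc = NULL, drop = ncol(bc)) {
  X <- bcDesign(bc, drop)
  C <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  if (is.null(A)) {
    fit <- stats::lm.fit(C, y)
    s2 <- sum(fit$residuals^2) / (n - ncol(C))
    V_beta <- s2 * chol2inv(qr.R(qr(C)))
  } else {
    if (is.null(vc)) vc <- remlVarianceComponents(y, C, A)
    eg <- eigen(A, symmetric = TRUE)
    v <- pmax(vc$lambda * eg$values, 0) + 1
    U <- eg$vectors
    Cs <- crossprod(U, C) / sqrt(v)
    ys <- crossprod(U, y)[, 1] / sqrt(v)
    fit <- stats::lm.fit(Cs, ys)
    s2 <- sum(fit$residuals^2) / (n - ncol(C))
    V_beta <- s2 * chol2inv(qr.R(qr(Cs)))
  }
  ix <- seq(2, ncol(C))
  b <- fit$coefficients[ix]
  w <- as.numeric(t(b) %*% solve(V_beta[ix, ix, drop = FALSE]) %*% b)
  list(wald = w, df = length(ix),
       p = stats::pchisq(w, df = length(ix), lower.tail = FALSE))
}

#' REML variance components via a single eigendecomposition
#'
#' Fits \code{y = C b + u + e} with \code{u ~ N(0, A sigma2_u)} and
#' \code{e ~ N(0, I sigma2_e)} by profiling the restricted likelihood over the
#' variance ratio \code{lambda = sigma2_u / sigma2_e} after rotating the data
#' once by the eigenvectors of A. With a kinship proportional to the identity
#' the two components are non-identifiable; this is detected (flat profile)
#' and flagged rather than silently returning an arbitrary split.
#'
#' @param y phenotype vector.
#' @param C fixed-effect design matrix (include the intercept column).
#' @param A additive relationship matrix (positive semi-definite).
#' @param interval search interval for log(lambda).
#' @param eigenA optional precomputed \code{eigen(A, symmetric = TRUE)}.
#' @return list with \code{sigma2_u}, \code{sigma2_e}, \code{lambda},
#'   \code{logLik}, \code{identifiable}, and the eigendecomposition
#'   (\code{eigenA}) for reuse.
#' @export
remlVarianceComponents <- function(y, C, A, interval = c(-12, 12),
                                   eigenA = NULL) {
  n <- length(y)
  if (is.null(dim(C))) C <- matrix(C, ncol = 1)
  p <- ncol(C)
  if (is.null(eigenA)) eigenA <- eigen(A, symmetric = TRUE)
  if (min(eigenA$values) < -1e-6 * max(abs(eigenA$values)))
    stop("A is not positive semi-definite")
  d <- pmax(eigenA$values, 0)
  U <- eigenA$vectors
  yt <- crossprod(U, y)[, 1]
  Ct <- crossprod(U, C)
  loglik <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1
    Cs <- Ct / sqrt(v)
    ys <- yt / sqrt(v)
    fit <- stats::lm.fit(Cs, ys)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    R <- qr.R(qr(Cs))
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(v)) +
              2 * sum(log(abs(diag(R)))))
  }
  grid <- seq(interval[1], interval[2], length.out = 25)
  lg <- vapply(grid, loglik, 0)
  if (diff(range(lg)) < 1e-6) {
    warning("variance components non-identifiable (flat REML profile)")
    return(list(sigma2_u = NA_real_, sigma2_e = NA_real_, lambda = NA_real_,
                logLik = lg[1], identifiable = FALSE, eigenA = eigenA))
  }
  lo <- grid[max(1, which.max(lg) - 1)]
  hi <- grid[min(length(grid), which.max(lg) + 1)]
  opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lam <- exp(opt$maximum)
  v <- lam * d + 1
  Cs <- Ct / sqrt(v)
  ys <- yt / sqrt(v)
  fit <- stats::lm.fit(Cs, ys)
  s2e <- sum(fit$residuals^2) / (n - p)
  list(sigma2_u = lam * s2e, sigma2_e = s2e, lambda = lam,
       logLik = opt$objective, identifiable = TRUE, eigenA = eigenA)
}

#' Mixed linear model association scan
#'
#' Generalized least squares per marker for \code{y = 1 mu [+ X beta] + Z u +
#' w a + e} with \code{u ~ N(0, A sigma2_u)}. In mode \code{"P3D"} (the
#' default) the variance ratio is estimated once under the no-marker null
#' model and reused for every marker; mode \code{"exact"} re-estimates it per
#' marker. With the ratio at zero the scan reduces exactly to the
#' corresponding OLS scan. With breed-composition columns supplied this is the
#' MLM_BC model.
#'
#' @param y phenotype vector.
#' @param W genotype dosage matrix.
#' @param A additive relationship matrix for the cohort.
#' @param bc optional breed-fraction matrix (adds BC fixed effects).
#' @param mode \code{"P3D"} or \code{"exact"}.
#' @param map optional per-marker map data.frame.
#' @param vc optional precomputed variance components (list with
#'   \code{lambda}) to reuse.
#' @param drop breed column dropped from the design.
#' @return scan data.frame (model tag "MLM" or "MLM_BC"); the variance
#'   components used are attached as attribute \code{"vc"}.
#' @export
mlmScan <- function(y, W, A, bc = NULL, mode = c("P3D", "exact"), map = NULL,
                    vc = NULL, drop = if (is.null(bc)) NULL else ncol(bc)) {
  mode <- match.arg(mode)
  n <- length(y)
  stopifnot(nrow(W) == n, nrow(A) == n)
  model <- if (is.null(bc)) "MLM" else "MLM_BC"
  C <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(bc)) C <- cbind(C, bcDesign(bc, drop))
  eigenA <- if (!is.null(vc) && !is.null(vc$eigenA)) vc$eigenA
            else eigen(A, symmetric = TRUE)
  if (is.null(vc)) vc <- remlVarianceComponents(y, C, A, eigenA = eigenA)
  if (mode == "P3D") {
    lam <- if (isTRUE(vc$identifiable)) vc$lambda else 0
    d <- pmax(eigenA$values, 0)
    v <- lam * d + 1
    U <- eigenA$vectors
    sw <- 1 / sqrt(v)
    ys <- crossprod(U, y)[, 1] * sw
    Cs <- crossprod(U, C) * sw
    Ws <- crossprod(U, W) * sw
    res <- .ols_scan(ys, Ws, Cs, model, map)
  } else {
    rows <- vector("list", ncol(W))
    for (k in seq_len(ncol(W))) {
      wk <- W[, k]
      if (stats::sd(wk) == 0) {
        rows[[k]] <- data.frame(marker = k, beta = NA_real_, se = NA_real_,
                                wald = NA_real_, p = NA_real_,
                                testable = FALSE, model = model)
        next
      }
      Ck <- cbind(C, marker = wk)
      vck <- remlVarianceComponents(y, Ck, A, eigenA = eigenA)
      lam <- if (isTRUE(vck$identifiable)) vck$lambda else 0
      v <- lam * pmax(eigenA$values, 0) + 1
      sw <- 1 / sqrt(v)
      U <- eigenA$vectors
      ys <- crossprod(U, y)[, 1] * sw
      Cs <- crossprod(U, Ck) * sw
      fit <- stats::lm.fit(Cs, ys)
      s2 <- sum(fit$residuals^2) / (n - ncol(Cs))
      Vb <- s2 * chol2inv(qr.R(qr(Cs)))
      b <- fit$coefficients["marker"]
      se <- sqrt(Vb[ncol(Cs), ncol(Cs)])
      wld <- (b / se)^2
      rows[[k]] <- data.frame(marker = k, beta = unname(b), se = se,
                              wald = unname(wld),
                              p = stats::pchisq(wld, 1, lower.tail = FALSE),
                              testable = TRUE, model = model)
    }
    res <- .attach_map(do.call(rbind, rows), map)
  }
  attr(res, "vc") <- vc[c("sigma2_u", "sigma2_e", "lambda", "identifiable")]
  res
}
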