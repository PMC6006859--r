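test_that("smaScan matches hand-solved normal equations on a worked example", {
  # 6 observations, one marker: solve (X'X) b = X'y directly
  w <- c(0, 1, 2, 1, 0, 2)
  y <- c(1.2, 2.1, 3.3, 1.9, 0.8, 3.6)
  X <- cbind(1, w)
  b <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% b
  s2 <- sum(resid^2) / (6 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  res <- smaScan(y, matrix(w, ncol = 1))
  expect_equal(res$beta, unname(b[2, 1]), tolerance = 1e-12)
  expect_equal(res$se, se, tolerance = 1e-12)
  expect_equal(res$wald, unname((b[2, 1] / se)^2), tolerance = 1e-12)
  # y exactly proportional to w: essentially zero p
  res2 <- smaScan(2.5 * w, matrix(w, ncol = 1))
  expect_lt(res2$p, 1e-20)
  # monomorphic marker flagged, not an exception
  res3 <- smaScan(y, cbind(w, rep(1, 6)))
  expect_false(res3$testable[2])
  expect_true(is.na(res3$p[2]))
})

test_that("null p-values are uniform", {
  set.seed(30)
  n <- 400
  W <- matrix(rbinom(n * 2000, 2, 0.4), n, 2000)
  y <- rnorm(n)
  res <- smaScan(y, W)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(qqData(res$p)$lambda, 1, tolerance = 0.1)
})

test_that("breed-composition covariates absorb stratification signal", {
  set.seed(31)
  n <- 300
  bc <- cbind(A = runif(n)); bc <- cbind(bc, B = 1 - bc[, 1])
  W <- matrix(rbinom(n * 50, 2, 0.3), n, 50)
  y <- 3 * bc[, 1] + rnorm(n)  # phenotype driven by ancestry only
  plain <- smaScan(y, W)
  adj <- smaBcScan(y, W, bc)
  expect_equal(adj$model[1], "SMA_BC")
  # marker p-values stay uniform once BC is modeled
  expect_gt(suppressWarnings(ks.test(adj$p, "punif"))$p.value, 0.01)
  # BC effect itself is highly significant
  expect_lt(bcEffectTest(y, bc)$p, 0.001)
  # single-breed BC carries no information: nests back to smaScan
  bc1 <- matrix(1, n, 1, dimnames = list(NULL, "A"))
  expect_equal(smaBcScan(y, W, bc1)$p, plain$p, tolerance = 1e-12)
  # collinear design is reported with the offending column
  bad <- cbind(bc, C = 0)
  bad[, 1] <- bad[, 1] - 0  # keep rows summing to 1 via zero column
  expect_error(smaBcScan(y, W, cbind(A = bc[, 1], B = bc[, 2] / 2,
                                     C = bc[, 2] / 2), drop = 3),
               "collinear")
})

test_that("REML recovers variance components and matches a grid oracle", {
  # half-sib-like kinship from a small pedigree
  set.seed(32)
  ped <- data.frame(
    id = c(sprintf("f%02d", 1:20), sprintf("o%03d", 1:180)),
    sire = c(rep(NA, 20), sprintf("f%02d", sample(1:10, 180, TRUE))),
    dam = c(rep(NA, 20), sprintf("f%02d", sample(11:20, 180, TRUE))),
    generation = rep(c(0, 1), c(20, 180)), stringsAsFactors = FALSE)
  subjects <- sprintf("o%03d", 1:180)
  A <- pedigreeA(ped, subjects)
  n <- length(subjects)
  Lc <- chol(A + diag(1e-8, n))
  reps <- replicate(8, {
    u <- as.vector(t(Lc) %*% rnorm(n)) * sqrt(3 / 7)
    y <- 2 + u + rnorm(n)
    vc <- remlVarianceComponents(y, matrix(1, n, 1), A)
    c(vc$sigma2_u, vc$sigma2_e)
  })
  expect_equal(mean(reps[1, ]), 3 / 7, tolerance = 0.4)
  expect_equal(mean(reps[2, ]), 1, tolerance = 0.25)
  # brute-force profile grid oracle on n = 50
  y50 <- (2 + as.vector(t(Lc) %*% rnorm(n)) + rnorm(n))[1:50]
  A50 <- A[1:50, 1:50]
  vc <- remlVarianceComponents(y50, matrix(1, 50, 1), A50)
  grid <- exp(seq(-12, 12, length.out = 4000))
  ll <- vapply(grid, function(lam) {
    eg <- eigen(A50, symmetric = TRUE)
    v <- pmax(eg$values, 0) * lam + 1
    yt <- crossprod(eg$vectors, y50)[, 1]
    Ct <- crossprod(eg$vectors, matrix(1, 50, 1))
    fit <- lm.fit(Ct / sqrt(v), yt / sqrt(v))
    s2 <- sum(fit$residuals^2) / 49
    -0.5 * (49 * (log(2 * pi * s2) + 1) + sum(log(v)) +
              log(sum((Ct / sqrt(v))^2)))
  }, 0)
  lam_grid <- grid[which.max(ll)]
  expect_equal(log(vc$lambda), log(lam_grid), tolerance = 0.05)
  expect_gte(vc$logLik + 1e-4, max(ll))
  # identity kinship: non-identifiable, flagged
  expect_warning(vc_id <- remlVarianceComponents(rnorm(50), matrix(1, 50, 1),
                                                 diag(50)),
                 "non-identifiable")
  expect_false(vc_id$identifiable)
})

test_that("mlmScan nests to OLS and matches an explicit GLS oracle", {
  set.seed(33)
  n <- 60
  A <- diag(n); A[1:30, 1:30] <- A[1:30, 1:30] + 0.4; diag(A) <- 1.4
  W <- matrix(rbinom(n * 12, 2, 0.45), n, 12)
  y <- rnorm(n) + W[, 3] * 0.5
  # sigma2_u = 0 reduces exactly to the simple regression scan
  res0 <- mlmScan(y, W, A, vc = list(lambda = 0, identifiable = TRUE,
                                     sigma2_u = 0, sigma2_e = 1))
  ols <- smaScan(y, W)
  expect_equal(res0$beta, ols$beta, tolerance = 1e-9)
  expect_equal(res0$p, ols$p, tolerance = 1e-9)
  # tiny-n GLS oracle with known V0 = lambda A + I
  lam <- 0.7
  n8 <- 8
  A8 <- A[1:n8, 1:n8]; W8 <- W[1:n8, 1:2]; y8 <- y[1:n8]
  res8 <- mlmScan(y8, W8, A8, vc = list(lambda = lam, identifiable = TRUE,
                                        sigma2_u = lam, sigma2_e = 1))
  V0i <- solve(lam * A8 + diag(n8))
  for (k in 1:2) {
    Xk <- cbind(1, W8[, k])
    bk <- solve(t(Xk) %*% V0i %*% Xk, t(Xk) %*% V0i %*% y8)
    r <- y8 - Xk %*% bk
    s2 <- as.numeric(t(r) %*% V0i %*% r) / (n8 - 2)
    sek <- sqrt(s2 * solve(t(Xk) %*% V0i %*% Xk)[2, 2])
    expect_equal(res8$beta[k], bk[2, 1], tolerance = 1e-8)
    expect_equal(res8$se[k], sek, tolerance = 1e-8)
  }
})

test_that("Wald statistic is invariant to allele-coding swaps", {
  set.seed(34)
  n <- 100
  W <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  y <- rnorm(n) + 0.4 * W[, 1]
  a <- smaScan(y, W)
  b <- smaScan(y, 2 - W)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("P3D and exact modes agree for small-effect markers", {
  set.seed(35)
  ped <- data.frame(
    id = c(sprintf("f%02d", 1:10), sprintf("o%03d", 1:80)),
    sire = c(rep(NA, 10), sprintf("f%02d", sample(1:5, 80, TRUE))),
    dam = c(rep(NA, 10), sprintf("f%02d", sample(6:10, 80, TRUE))),
    generation = rep(c(0, 1), c(10, 80)), stringsAsFactors = FALSE)
  subjects <- sprintf("o%03d", 1:80)
  A <- pedigreeA(ped, subjects)
  n <- 80
  u <- as.vector(t(chol(A + diag(1e-8, n))) %*% rnorm(n)) * 0.6
  W <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  y <- 1 + u + rnorm(n)
  p3d <- mlmScan(y, W, A, mode = "P3D")
  exact <- mlmScan(y, W, A, mode = "exact")
  keep <- !is.na(p3d$p)
  expect_equal(p3d$p[keep], exact$p[keep], tolerance = 0.1)
})
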