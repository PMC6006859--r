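make_null_scan <- function(nchr = 3, per_chr = 100, chr_offset = 3,
                           p = NULL, pip = NULL) {
  chr <- rep(chr_offset + seq_len(nchr), each = per_chr)
  pos <- rep(seq(0.5, by = 1, length.out = per_chr), nchr)
  toyScan(chr, pos, p = p, pip = pip)
}

test_that("NCHR threshold equals the pooled bin-extreme quantile", {
  # all p identical: threshold is that constant
  sc <- make_null_scan(p = rep(0.2, 300))
  thr <- nchrThreshold(sc, binMarkers = 10)
  expect_equal(thr$value, 0.2)
  expect_equal(thr$method, "NCHR")
  # type-7 quantile convention on a known synthetic list
  expect_equal(unname(quantile(seq(0.01, 1, by = 0.01), 0.05, type = 7)),
               0.0595)
  # bin minima of uniforms follow Beta(1, binMarkers): 5% quantile matches
  set.seed(50)
  scans <- replicate(20, make_null_scan(p = runif(300)), simplify = FALSE)
  thr2 <- nchrThreshold(scans, binMarkers = 40)
  expect_equal(thr2$nBins, 20 * 3 * 2)  # 100 %/% 40 = 2 complete bins per chr
  expect_equal(thr2$value, qbeta(0.05, 1, 40), tolerance = 0.4)
  # PIP scale takes bin maxima and the upper quantile
  scans_pip <- replicate(10, make_null_scan(pip = runif(300)),
                         simplify = FALSE)
  thr3 <- nchrThreshold(scans_pip, binMarkers = 40, scale = "pip")
  expect_equal(thr3$value, qbeta(0.95, 40, 1), tolerance = 0.05)
  expect_gt(thr3$value, 0.9)
  expect_error(nchrThreshold(sc, nullChr = 12), "no complete")
})

test_that("NCHR threshold is monotone in the input statistics", {
  set.seed(51)
  p <- runif(300)
  t1 <- nchrThreshold(make_null_scan(p = p), binMarkers = 20)$value
  t2 <- nchrThreshold(make_null_scan(p = p / 2), binMarkers = 20)$value
  expect_lt(t2, t1)
})

test_that("NCHR thresholds calibrate family-wise error on fresh null data", {
  # closed loop: build the threshold from 20 null replicates, then measure
  # how often a fresh null replicate exceeds it anywhere in a bin
  set.seed(52)
  scans <- replicate(20, make_null_scan(p = runif(300)), simplify = FALSE)
  thr <- nchrThreshold(scans, binMarkers = 20)
  hits <- replicate(600, min(runif(20)) < thr$value)
  expect_equal(mean(hits), 0.05, tolerance = 0.35)
})

test_that("Meff reaches the independence and degeneracy limits", {
  set.seed(53)
  n <- 2000
  # independent markers: Meff ~ panel size
  W <- matrix(rbinom(n * 60, 2, 0.5), n, 60)
  map <- data.frame(chr = 1, pos = seq_len(60))
  m_ind <- slideMeff(W, map, windowMarkers = 8, nMc = 40000, seed = 1)
  expect_equal(m_ind$meff, 60, tolerance = 0.2)
  # perfectly correlated markers: Meff ~ 1
  w <- rbinom(n, 2, 0.5)
  W1 <- matrix(w, n, 10)
  m_one <- slideMeff(W1, data.frame(chr = 1, pos = 1:10),
                     windowMarkers = 5, nMc = 40000, seed = 2)
  expect_equal(m_one$meff, 1, tolerance = 0.15)
  # two independent blocks of perfectly correlated markers: exact oracle
  # P(max of two |Z| > t) = 0.05  =>  alpha* = 1 - sqrt(0.95), Meff = 1.975
  w2 <- rbinom(n, 2, 0.5)
  W2 <- cbind(W1[, 1:5], matrix(w2, n, 5))
  m_two <- slideMeff(W2, data.frame(chr = rep(1:2, each = 5), pos = rep(1:5, 2)),
                     windowMarkers = 5, nMc = 40000, seed = 3)
  oracle <- 0.05 / (1 - sqrt(0.95))
  expect_equal(m_two$meff, oracle, tolerance = 0.1)
  expect_error(slideMeff(W, map, windowMarkers = 100), "window exceeds")
})

test_that("Meff is invariant to marker order reversal and allele flips", {
  set.seed(54)
  n <- 800
  base <- matrix(rbinom(n * 30, 2, 0.5), n, 30)
  W <- base + cbind(0, base[, -30]) %% 3  # locally correlated
  W <- pmin(W, 2)
  map <- data.frame(chr = 1, pos = 1:30)
  a <- slideMeff(W, map, windowMarkers = 6, nMc = 30000, seed = 5)$meff
  b <- slideMeff(W[, 30:1], data.frame(chr = 1, pos = 1:30),
                 windowMarkers = 6, nMc = 30000, seed = 5)$meff
  d <- slideMeff(2 - W, map, windowMarkers = 6, nMc = 30000, seed = 5)$meff
  expect_equal(b, a, tolerance = 0.1)
  expect_equal(d, a, tolerance = 1e-8)
})

test_that("Bonferroni thresholds divide alpha by Meff", {
  expect_equal(bonferroniThreshold(1000)$value, 5e-5)
  expect_equal(bonferroniThreshold(1)$value, 0.05)
  expect_equal(bonferroniThreshold(5985)$value, 0.05 / 5985)
  expect_error(bonferroniThreshold(0.5), ">= 1")
})

test_that("qqData returns calibrated expectations and inflation", {
  set.seed(55)
  u <- runif(5000)
  qq <- qqData(u)
  expect_equal(qq$lambda, 1, tolerance = 0.05)
  expect_equal(qq$data$observed, qq$data$expected, tolerance = 0.2)
  # uniformly tiny p-values: flat elevated line
  flat <- qqData(rep(1e-6, 100))
  expect_true(all(flat$data$observed == 6))
  # 10% inflated mixture pushes lambda above 1, matching a chi-square oracle
  infl <- c(runif(4500), pchisq(rchisq(500, 1, ncp = 8), 1, lower.tail = FALSE))
  qi <- qqData(infl)
  oracle_lambda <- median(qchisq(infl, 1, lower.tail = FALSE)) /
    qchisq(0.5, 1, lower.tail = FALSE)
  expect_equal(qi$lambda, oracle_lambda)
  expect_gt(qi$lambda, 1.05)
  expect_warning(qqData(c(0, 0.5)), "clipped")
  expect_error(qqData(c(0.5, 1.2)), "must be in")
})
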