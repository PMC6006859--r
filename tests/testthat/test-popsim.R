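test_that("base population draws alleles at frequency 0.5 and is reproducible", {
  gm <- toyGenome(nChr = 2, markersPerChr = 500L)
  set.seed(7)
  pop <- initBasePopulation(200, gm)
  f <- alleleFreqs(pop)
  expect_equal(mean(f), 0.5, tolerance = 0.01)
  expect_equal(nInd(pop), 200L)
  expect_true(all(pop@pedigree$generation == 0))
  # determinism under a fixed seed
  set.seed(123)
  a <- initBasePopulation(2, toyGenome(markersPerChr = 1L))
  set.seed(123)
  b <- initBasePopulation(2, toyGenome(markersPerChr = 1L))
  expect_identical(haplotypes(a), haplotypes(b))
  expect_error(initBasePopulation(0, gm), "at least 2")
})

test_that("meiosis respects homozygosity and boundary mutation rates", {
  gm <- toyGenome(markersPerChr = 30L, mutationRate = 0)
  hom <- matrix(1L, 30, 2)
  set.seed(1)
  g <- meiosis(hom, gm)
  expect_identical(as.integer(g), rep(1L, 30))
  # mutation rate 1 always flips
  gm1 <- toyGenome(markersPerChr = 1L, mutationRate = 1)
  g1 <- meiosis(matrix(0L, 1, 2), gm1)
  expect_identical(as.integer(g1), 1L)
  expect_error(meiosis(matrix(0L, 5, 2), gm), "matrix matching")
})

test_that("recombination fraction follows the binomial map function", {
  # two loci 50 cM apart on a 100-cM chromosome, crossover cap 4:
  # r(d) = 0.5 * (1 - (1 - 2 d / N)^N), d in Morgan
  gm <- GenomeMap(nChr = 1, chrLength = 100, positions = list(c(25, 75)),
                  mutationRate = 0)
  het <- matrix(c(1L, 1L, 0L, 0L), 2, 2)  # haplotypes 11 and 00
  set.seed(42)
  n <- 20000
  rec <- 0
  for (i in seq_len(n)) {
    g <- as.integer(meiosis(het, gm))
    if (g[1] != g[2]) rec <- rec + 1
  }
  expected <- 0.5 * (1 - (1 - 2 * 0.5 / 4)^4)  # 0.3418
  expect_equal(rec / n, expected, tolerance = 0.03)
})

test_that("random mating has no selfing and tracks generations", {
  gm <- toyGenome(markersPerChr = 10L)
  set.seed(3)
  pop <- initBasePopulation(2, gm)
  off <- randomMate(pop, nOffspring = 1)
  ped <- pedigree(off)
  kid <- ped[ped$generation == 1, ]
  expect_equal(nrow(kid), 1)
  expect_false(kid$sire == kid$dam)
  big <- randomMate(initBasePopulation(50, gm), nOffspring = 80)
  expect_equal(nInd(big), 80L)
  expect_equal(big@generation, 1L)
  lone <- toyPopulation(matrix(0L, 10, 2), gm)
  expect_error(randomMate(lone, 1), "at least 2 parents")
})

test_that("drift matches the Wright-Fisher variance closed form", {
  # many replicate neutral loci under pure drift: Var(p_t) = p0 q0 (1-(1-1/2N)^t)
  gm <- toyGenome(nChr = 1, markersPerChr = 400L, mutationRate = 0)
  set.seed(9)
  pop <- initBasePopulation(50, gm)
  pop <- randomMate(pop, generations = 60, recordPedigree = FALSE)
  f <- alleleFreqs(pop)
  expect_gt(mean(f == 0 | f == 1), 0.05)  # fixation well underway
  expected_var <- 0.25 * (1 - (1 - 1 / 100)^60)
  expect_equal(var(f), expected_var, tolerance = 0.25)
  # symmetric mutation-drift keeps the mean frequency a martingale at 0.5
  expect_equal(mean(f), 0.5, tolerance = 0.05)
})

test_that("breed founding yields labeled subsamples that diverge by drift", {
  gm <- toyGenome(nChr = 2, markersPerChr = 100L, mutationRate = 2.5e-5)
  set.seed(5)
  base <- initBasePopulation(120, gm)
  base <- randomMate(base, generations = 20, recordPedigree = FALSE)
  # generations = 0: breeds are subsamples of the base
  b0 <- foundBreeds(base, 2, 30, 0)
  expect_equal(names(b0), c("A", "B"))
  expect_equal(nInd(b0$A), 30L)
  base_cols <- apply(haplotypes(base), 2, paste, collapse = "")
  a_cols <- apply(haplotypes(b0$A), 2, paste, collapse = "")
  expect_true(all(a_cols %in% base_cols))
  expect_equal(unname(breedFractions(b0$A)[1, ]), c(1, 0))
  expect_error(foundBreeds(base, 2, 500, 0), "exceeds")
  # F_ST grows with divergence time (drift expectation 1-(1-1/2Ne)^t)
  set.seed(6)
  b_short <- foundBreeds(base, 2, 25, 5)
  set.seed(6)
  b_long <- foundBreeds(base, 2, 25, 40)
  expect_gt(fstPairwise(b_long)[1, 2], fstPairwise(b_short)[1, 2])
})

test_that("half-sib expansion produces the expected family structure", {
  gm <- toyGenome(markersPerChr = 20L)
  set.seed(8)
  breed <- initBasePopulation(100, gm)
  off <- expandHalfSib(breed, n = 1000, nSires = 50)
  ped <- pedigree(off)
  kids <- ped[ped$generation == 1, ]
  fam <- table(kids$sire)
  expect_equal(mean(fam), 20, tolerance = 0.15)
  expect_lte(length(fam), 50)
  # family sizes consistent with Multinomial(1000, 1/50)
  expect_equal(var(as.numeric(fam)), 1000 * (1 / 50) * (49 / 50),
               tolerance = 0.5)
  # dams are never sires
  expect_length(intersect(unique(kids$sire), unique(kids$dam)), 0)
  one <- expandHalfSib(breed, n = 20, nSires = 1)
  expect_equal(length(unique(pedigree(one)$sire[21:40])), 1)
  expect_error(expandHalfSib(breed, 10, nSires = 200), "exceeds")
})

test_that("crossing averages breed fractions through arbitrary sequences", {
  gm <- toyGenome(markersPerChr = 10L)
  set.seed(2)
  base <- initBasePopulation(80, gm)
  br <- foundBreeds(base, 4, 20, 0)
  ab <- crossPopulations(br$A, br$B, 30, "AB")
  expect_equal(unname(breedFractions(ab)[5, ]), c(0.5, 0.5, 0, 0))
  aba <- crossPopulations(ab, br$A, 30, "(AB)A")
  expect_equal(unname(breedFractions(aba)[1, ]), c(0.75, 0.25, 0, 0))
  cd <- crossPopulations(br$C, br$D, 30, "CD")
  abcd <- crossPopulations(ab, cd, 30, "(AB)(CD)")
  expect_equal(unname(breedFractions(abcd)[7, ]), rep(0.25, 4))
  expect_true(all(abs(rowSums(breedFractions(abcd)) - 1) < 1e-12))
  expect_error(crossPopulations(br$A, br$B, 0), "must be positive|invalid")
})

test_that("admixed sampling pools populations with correct bookkeeping", {
  gm <- toyGenome(markersPerChr = 10L)
  set.seed(4)
  base <- initBasePopulation(100, gm)
  br <- foundBreeds(base, 4, 25, 0)
  ab <- crossPopulations(br$A, br$B, 25, "AB")
  aba <- crossPopulations(ab, br$A, 25, "(AB)A")
  abc <- crossPopulations(ab, br$C, 25, "(AB)C")
  cd <- crossPopulations(br$C, br$D, 25, "CD")
  abcd <- crossPopulations(ab, cd, 25, "(AB)(CD)")
  pool <- c(br, list(ab, aba, abc, abcd))
  adm <- buildAdmixed(pool, 120)
  expect_equal(nInd(adm), 120L)
  # expected breed-A mean over the 8 equal pools:
  # (1 + 0 + 0 + 0 + 0.5 + 0.75 + 0.25 + 0.25) / 8
  all_fracs <- do.call(rbind, lapply(pool, breedFractions))
  expect_equal(mean(all_fracs[, "A"]), 2.75 / 8)
  expect_equal(mean(breedFractions(adm)[, "A"]), 2.75 / 8, tolerance = 0.08)
  expect_error(buildAdmixed(pool, 1e6), "exceeds")
  # single-source pool: a plain subsample
  sub <- buildAdmixed(list(br$A), 10)
  expect_true(all(sub@ids %in% br$A@ids))
})

test_that("panel selection returns evenly spread segregating loci", {
  gm <- toyGenome(nChr = 2, markersPerChr = 100L)
  set.seed(10)
  pop <- initBasePopulation(50, gm)
  pop <- randomMate(pop, generations = 30, recordPedigree = FALSE)
  f <- alleleFreqs(pop)
  nseg <- min(table(markerMap(gm)$chr[f > 0 & f < 1]))
  panel <- selectMarkerPanel(pop, 20)
  expect_length(panel, 40)
  pf <- alleleFreqs(pop, panel)
  expect_true(all(pf > 0 & pf < 1))
  # identity case: ask for every segregating locus
  all_panel <- selectMarkerPanel(pop, nseg)
  expect_length(all_panel, 2 * nseg)
  expect_error(selectMarkerPanel(pop, 101), "segregating")
})

test_that("pedigree A matches textbook values and a path-counting oracle", {
  ped <- data.frame(
    id = c("s", "d", "o1", "o2", "d2", "h"),
    sire = c(NA, NA, "s", "s", NA, "s"),
    dam = c(NA, NA, "d", "d", NA, "d2"),
    generation = c(0, 0, 1, 1, 0, 1),
    stringsAsFactors = FALSE)
  A <- pedigreeA(ped, ped$id)
  expect_equal(A["s", "o1"], 0.5)   # parent-offspring
  expect_equal(A["o1", "o2"], 0.5)  # full sibs
  expect_equal(A["o1", "h"], 0.25)  # half sibs
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) >= 1 & diag(A) <= 2))

  # 3-generation pedigree vs independent recursive coancestry oracle
  ped3 <- data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g"),
    sire = c(NA, NA, "a", "a", "c", "c", "e"),
    dam = c(NA, NA, "b", "b", "d", "d", "f"),
    generation = c(0, 0, 1, 1, 2, 2, 3),
    stringsAsFactors = FALSE)
  coan <- function(i, j) {
    # recursive kinship; founders unrelated, non-inbred
    geti <- function(x) ped3[ped3$id == x, ]
    if (i == j) {
      r <- geti(i)
      return(0.5 * (1 + if (is.na(r$sire)) 0 else coan(r$sire, r$dam)))
    }
    ri <- geti(i); rj <- geti(j)
    # recurse on the later-generation member
    if (ri$generation < rj$generation) { tmp <- ri; ri <- rj; rj <- tmp }
    if (is.na(ri$sire)) return(0)
    0.5 * (coan(ri$sire, rj$id) + coan(ri$dam, rj$id))
  }
  A3 <- pedigreeA(ped3, ped3$id)
  for (i in ped3$id) for (j in ped3$id)
    expect_equal(A3[i, j], 2 * coan(i, j) * (if (i == j) 1 else 1),
                 tolerance = 1e-12,
                 info = paste(i, j))
  # diagonal uses 1 + F rather than 2*kinship
  for (i in ped3$id)
    expect_equal(A3[i, i], 2 * coan(i, i), tolerance = 1e-12)
  # positive semi-definite
  expect_gte(min(eigen(A3, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(pedigreeA(ped, c("s", "nope")), "unknown")
})
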