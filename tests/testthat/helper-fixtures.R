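# Shared fixtures, computed lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# tiny genome for unit tests
toyGenome <- function(nChr = 1L, chrLength = 100, markersPerChr = 20L,
                      mutationRate = 0) {
  GenomeMap(nChr = nChr, chrLength = chrLength,
            markersPerChr = markersPerChr, mutationRate = mutationRate)
}

# population with explicitly supplied haplotypes (loci x 2n, 0/1)
toyPopulation <- function(haps, genome, label = "T") {
  h <- matrix(as.raw(haps), nrow = nrow(haps))
  n <- ncol(h) / 2
  ids <- sprintf("%s_%03d", label, seq_len(n))
  new("Population", haplotypes = h, genome = genome, ids = ids,
      pedigree = data.frame(id = ids, sire = NA_character_,
                            dam = NA_character_, generation = 0L,
                            pop = label, stringsAsFactors = FALSE),
      breedFractions = matrix(numeric(0), nrow = n, ncol = 0),
      generation = 0L, label = label)
}

# a synthetic scan-result data.frame on a regular marker grid
toyScan <- function(chr, pos, p = NULL, pip = NULL) {
  df <- data.frame(marker = seq_along(chr), chr = chr, pos = pos)
  if (!is.null(p)) df$p <- p
  if (!is.null(pip)) df$pip <- pip
  df
}

thresholdSet <- function(value, scale = "p", method = "NCHR", level = 0.05) {
  structure(list(method = method, scale = scale, level = level,
                 value = value), class = "ThresholdSet")
}

# Full study-conditions demography (the conditions of the simulated
# experiment: 1000 generations of burn-in at Ne = 1000, four breeds diverged
# 50 generations at Ne = 100, half-sib expansion to 1000, crossing, and an
# admixed sample of 1000) on a thinned marker grid of 250 loci per
# chromosome. Used by the LD, divergence and calibration checks.
studyFixture <- function() {
  memo("study", {
    set.seed(1)
    gm <- GenomeMap(nChr = 6, chrLength = 100, markersPerChr = 250)
    base <- initBasePopulation(1000, gm)
    base <- randomMate(base, generations = 1000, recordPedigree = FALSE)
    breeds <- foundBreeds(base, 4, 100, 50)
    fst <- fstPairwise(breeds)
    e51 <- lapply(breeds, expandHalfSib, n = 1000, nSires = 50)
    p52 <- lapply(e51, randomMate, nOffspring = 1000)
    ab52 <- crossPopulations(e51[[1]], e51[[2]], 1000, "AB")
    cd52 <- crossPopulations(e51[[3]], e51[[4]], 1000, "CD")
    p53 <- lapply(p52, randomMate, nOffspring = 1000)
    pool <- c(p53, list(
      AB = crossPopulations(p52[[1]], p52[[2]], 1000, "AB"),
      ABA = crossPopulations(ab52, p52[[1]], 1000, "(AB)A"),
      ABC = crossPopulations(ab52, p52[[3]], 1000, "(AB)C"),
      ABCD = crossPopulations(ab52, cd52, 1000, "(AB)(CD)")))
    admx <- buildAdmixed(pool, 1000)
    pb <- p53[[1]]
    panel <- selectMarkerPanel(admx, 200)
    arch <- selectQtl(admx, panel, qtlTargets(), 0.02)
    panel2 <- dropQtlFromPanel(panel, arch)
    arch <- standardizeEffects(admx, arch)
    phen_admx <- simulatePhenotypes(admx, arch)
    phen_pb <- simulatePhenotypes(pb, arch)
    list(genome = gm, breeds = breeds, fst = fst, admx = admx, pb = pb,
         panel = panel, panel2 = panel2, arch = arch,
         phen_admx = phen_admx, phen_pb = phen_pb)
  })
}

# reduced-scale end-to-end experiment (the `ci` preset)
ciResult <- function() {
  memo("ci", runExperiment(ciConfig(1)))
}
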