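#' Experiment configuration
#'
#' Collects every tunable of the end-to-end study: genome, demography, trait
#' architecture, models, thresholds, chain settings, replication and the
#' master seed. The defaults are the full study conditions (six 100-cM
#' chromosomes with 5000 markers each, 1000 generations of burn-in at Ne =
#' 1000, four breeds diverged 50 generations at Ne = 100, half-sib expansion
#' to 1000, an admixed sample of 1000, heritability 0.30, 32 datasets x 20
#' replicates, 100k/10k chains); [ciConfig()] and [deskConfig()] provide
#' reduced-scale presets.
#'
#' @param nChr,chrLength,markersPerChr,maxCrossovers,mutationRate genome
#'   parameters (see [GenomeMap()]).
#' @param baseN,burnInGens base-population size and burn-in generations.
#' @param nBreeds,breedN,breedGens breed founding and divergence.
#' @param expandN,nSires half-sib expansion cohort size and sire count.
#' @param crossN,admixN cross cohort sizes and admixed sample size.
#' @param panelPerChr association panel markers per chromosome.
#' @param targets QTL targets (see [qtlTargets()]).
#' @param h2,mafMin trait heritability and QTL MAF floor.
#' @param models subset of \code{c("sma","sma_bc","mlm","mlm_bc","bmr","bmr_bc")}.
#' @param thresholdMethods subset of \code{c("nchr","slide")} ("slide" applies
#'   to the frequentist models only).
#' @param binMarkers NCHR bin size in markers; \code{NULL} = markers spanning
#'   4 cM at the panel density.
#' @param chainLength,burnIn MCMC settings for the Bayesian models.
#' @param slideNMc Monte-Carlo cycles for the Meff estimator.
#' @param nDatasets,nReplicates replication structure.
#' @param masterSeed master seed; every stage seed is derived from it.
#' @return list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(nChr = 6L, chrLength = 100, markersPerChr = 5000L,
                             maxCrossovers = 4L, mutationRate = 2.5e-5,
                             baseN = 1000L, burnInGens = 1000L,
                             nBreeds = 4L, breedN = 100L, breedGens = 50L,
                             expandN = 1000L, nSires = 50L,
                             crossN = 1000L, admixN = 1000L,
                             panelPerChr = 1000L,
                             targets = qtlTargets(), h2 = 0.30, mafMin = 0.02,
                             models = c("sma", "sma_bc", "mlm", "mlm_bc",
                                        "bmr", "bmr_bc"),
                             thresholdMethods = "nchr", binMarkers = NULL,
                             chainLength = 100000L, burnIn = 10000L,
                             slideNMc = 100000L,
                             nDatasets = 32L, nReplicates = 20L,
                             masterSeed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  thresholdMethods <- match.arg(thresholdMethods, c("nchr", "slide"),
                                several.ok = TRUE)
  targets <- data.frame(chr = as.integer(targets$chr),
                        pos = as.numeric(targets$pos),
                        varFraction = as.numeric(targets$varFraction))
  cfg <- list(nChr = as.integer(nChr), chrLength = as.numeric(chrLength),
              markersPerChr = as.integer(markersPerChr),
              maxCrossovers = as.integer(maxCrossovers),
              mutationRate = mutationRate,
              baseN = as.integer(baseN), burnInGens = as.integer(burnInGens),
              nBreeds = as.integer(nBreeds), breedN = as.integer(breedN),
              breedGens = as.integer(breedGens),
              expandN = as.integer(expandN), nSires = as.integer(nSires),
              crossN = as.integer(crossN), admixN = as.integer(admixN),
              panelPerChr = as.integer(panelPerChr),
              targets = targets, h2 = as.numeric(h2),
              mafMin = as.numeric(mafMin),
              models = models, thresholdMethods = thresholdMethods,
              binMarkers = if (is.null(binMarkers)) NULL else as.integer(binMarkers),
              chainLength = as.integer(chainLength),
              burnIn = as.integer(burnIn), slideNMc = as.integer(slideNMc),
              nDatasets = as.integer(nDatasets),
              nReplicates = as.integer(nReplicates),
              masterSeed = as.integer(masterSeed))
  counts <- c(cfg$nChr, cfg$markersPerChr, cfg$baseN, cfg$nBreeds, cfg$breedN,
              cfg$expandN, cfg$nSires, cfg$crossN, cfg$admixN, cfg$panelPerChr,
              cfg$chainLength, cfg$nDatasets, cfg$nReplicates)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$burnIn >= cfg$chainLength) stop("burnIn must be below chainLength")
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stop("h2 must be in (0, 1)")
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' @describeIn experimentConfig small smoke-scale preset that completes in
#'   minutes on one CPU.
#' @export
ciConfig <- function(masterSeed = 1L) {
  experimentConfig(markersPerChr = 400L, baseN = 150L, burnInGens = 150L,
                   breedN = 50L, expandN = 300L, nSires = 15L, crossN = 300L,
                   admixN = 400L, panelPerChr = 200L,
                   chainLength = 4000L, burnIn = 800L, slideNMc = 20000L,
                   nDatasets = 2L, nReplicates = 3L, masterSeed = masterSeed)
}

#' @describeIn experimentConfig desk-scale preset (hours on one CPU):
#'   4 datasets x 5 replicates, 20k/2k chains, thinned genome.
#' @export
deskConfig <- function(masterSeed = 1L) {
  experimentConfig(markersPerChr = 1000L, baseN = 1000L, burnInGens = 1000L,
                   panelPerChr = 1000L, chainLength = 20000L, burnIn = 2000L,
                   nDatasets = 4L, nReplicates = 5L, masterSeed = masterSeed)
}

#' Write / read an experiment configuration as JSON
#'
#' @param cfg an \code{"ExperimentConfig"}.
#' @param path file path.
#' @return \code{readConfig} returns the configuration.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$targets <- as.data.frame(raw$targets)
  do.call(experimentConfig, raw[!vapply(raw, is.null, TRUE)])
}

# deterministic per-stage seed derivation from the master seed
.stage_seed <- function(master, stage, dataset = 0L, replicate = 0L) {
  codes <- c(base = 1, breeds = 2, cross = 3, trait = 4, scan = 5, bayes = 6,
             slide = 7)
  s <- (as.double(master %% 100003L) * 98317 + dataset * 7919 +
          replicate * 613 + codes[[stage]] * 31) %% 2147483646
  as.integer(s) + 1L
}

.auto_bin <- function(cfg) {
  if (!is.null(cfg$binMarkers)) return(cfg$binMarkers)
  max(2L, as.integer(round(4 * cfg$panelPerChr / max(cfg$chrLength))))
}

# simulate one replicate's training data from a dataset's breeds
.simulate_replicate <- function(cfg, breeds, d, r) {
  set.seed(.stage_seed(cfg$masterSeed, "cross", d, r))
  exp51 <- lapply(breeds, expandHalfSib, n = cfg$expandN, nSires = cfg$nSires)
  pure52 <- lapply(exp51, randomMate, nOffspring = cfg$crossN)
  ab52 <- crossPopulations(exp51[[1]], exp51[[2]], cfg$crossN, "AB")
  cd52 <- crossPopulations(exp51[[3]], exp51[[4]], cfg$crossN, "CD")
  pure53 <- lapply(pure52, randomMate, nOffspring = cfg$crossN)
  ab53 <- crossPopulations(pure52[[1]], pure52[[2]], cfg$crossN, "AB")
  aba <- crossPopulations(ab52, pure52[[1]], cfg$crossN, "(AB)A")
  abc <- crossPopulations(ab52, pure52[[3]], cfg$crossN, "(AB)C")
  abcd <- crossPopulations(ab52, cd52, cfg$crossN, "(AB)(CD)")
  pool <- c(pure53, list(AB = ab53, ABA = aba, ABC = abc, ABCD = abcd))
  admx <- buildAdmixed(pool, cfg$admixN)
  panel <- selectMarkerPanel(admx, cfg$panelPerChr)
  arch <- selectQtl(admx, panel, cfg$targets, cfg$mafMin, cfg$h2)
  panel <- dropQtlFromPanel(panel, arch)
  set.seed(.stage_seed(cfg$masterSeed, "trait", d, r))
  arch <- standardizeEffects(admx, arch)
  phen <- simulatePhenotypes(admx, arch)
  list(admx = admx, pb = pure53[[1]], panel = panel, arch = arch, phen = phen)
}

# run the configured scans on one replicate's admixed cohort
.scan_replicate <- function(cfg, rep_data, d, r) {
  admx <- rep_data$admx
  panel <- rep_data$panel
  W <- genotypes(admx, panel)
  mapP <- markerMap(admx@genome)[panel, , drop = FALSE]
  y <- rep_data$phen$y
  bc <- breedFractions(admx)
  out <- list()
  set.seed(.stage_seed(cfg$masterSeed, "scan", d, r))
  need_mlm <- any(c("mlm", "mlm_bc") %in% cfg$models)
  if (need_mlm) {
    A <- pedigreeA(admx, admx@ids)
    eigenA <- eigen(A, symmetric = TRUE)
  }
  for (m in cfg$models) {
    out[[m]] <- switch(m,
      sma = smaScan(y, W, mapP),
      sma_bc = smaBcScan(y, W, bc, mapP),
      mlm = mlmScan(y, W, A, map = mapP, vc = remlVarianceComponents(
        y, matrix(1, length(y), 1), A, eigenA = eigenA)),
      mlm_bc = mlmScan(y, W, A, bc = bc, map = mapP,
                       vc = remlVarianceComponents(
        y, cbind(1, bcDesign(bc)), A, eigenA = eigenA)),
      bmr = ,
      bmr_bc = {
        priors <- deriveHyperparameters(
          cfg$h2 / (1 - cfg$h2), nrow(cfg$targets), colMeans(W) / 2)
        fit <- gibbsBayesCpi(y, W, bc = if (m == "bmr_bc") bc else NULL,
                             priors = priors, chainLength = cfg$chainLength,
                             burnIn = cfg$burnIn,
                             seed = .stage_seed(cfg$masterSeed, "bayes", d,
                                                r + if (m == "bmr_bc") 1000L else 0L),
                             map = mapP)
        fit$markers
      })
  }
  out
}

#' Run the configured experiment end to end
#'
#' For each dataset: founds fresh breeds from the shared burned-in base
#' population (datasets differ only by their derived seeds, which refreshes
#' breed allele frequencies and hence realized QTL minor allele frequencies);
#' for each replicate: half-sib expansion, crossing, admixture, panel and QTL
#' selection, phenotypes, and all configured scans; then dataset-level
#' thresholds (NCHR per model; SLIDE-based Bonferroni for frequentist models)
#' and the power/FPR/accuracy/PPV scoring. Deterministic given
#' \code{masterSeed}.
#'
#' @param cfg an \code{"ExperimentConfig"}.
#' @param verbose print stage progress.
#' @return list of class \code{"ExperimentResult"} with \code{config},
#'   \code{performance} (per dataset x model x method), \code{summary}
#'   (means and SEs across datasets), and \code{datasets} (per-dataset scan
#'   results, thresholds, architectures, report data).
#' @export
runExperiment <- function(cfg, verbose = FALSE) {
  stopifnot(is(cfg, "ExperimentConfig"))
  genome <- GenomeMap(cfg$nChr, cfg$chrLength, cfg$markersPerChr,
                      cfg$maxCrossovers, cfg$mutationRate)
  say <- function(...) if (verbose) message(sprintf(...))
  say("burn-in: %d individuals, %d generations", cfg$baseN, cfg$burnInGens)
  set.seed(.stage_seed(cfg$masterSeed, "base"))
  base <- initBasePopulation(cfg$baseN, genome)
  base <- randomMate(base, generations = cfg$burnInGens, recordPedigree = FALSE)
  bin <- .auto_bin(cfg)
  nullChr <- setdiff(seq_len(cfg$nChr), sort(unique(cfg$targets$chr)))
  perf <- list()
  datasets <- vector("list", cfg$nDatasets)
  for (d in seq_len(cfg$nDatasets)) {
    say("dataset %d/%d", d, cfg$nDatasets)
    set.seed(.stage_seed(cfg$masterSeed, "breeds", d))
    breeds <- foundBreeds(base, cfg$nBreeds, cfg$breedN, cfg$breedGens)
    reps <- vector("list", cfg$nReplicates)
    for (r in seq_len(cfg$nReplicates)) {
      rd <- .simulate_replicate(cfg, breeds, d, r)
      scans <- .scan_replicate(cfg, rd, d, r)
      meff <- NULL
      if ("slide" %in% cfg$thresholdMethods) {
        freq_models <- intersect(cfg$models, c("sma", "sma_bc", "mlm", "mlm_bc"))
        if (length(freq_models)) {
          W <- genotypes(rd$admx, rd$panel)
          mapP <- markerMap(genome)[rd$panel, , drop = FALSE]
          meff <- slideMeff(W, mapP, windowMarkers = .auto_bin(cfg),
                            nMc = cfg$slideNMc,
                            seed = .stage_seed(cfg$masterSeed, "slide", d, r))
        }
      }
      reps[[r]] <- list(results = scans, arch = rd$arch, meff = meff,
                        phen = rd$phen[, c("tbv", "y")])
    }
    sc <- .score_dataset(cfg, genome, reps, nullChr, bin, d)
    thresholds <- sc$thresholds
    rows <- sc$rows
    perf[[d]] <- do.call(rbind, rows)
    perf[[d]]$dataset <- d
    datasets[[d]] <- list(replicates = reps, thresholds = thresholds)
  }
  performance <- do.call(rbind, perf)
  out <- list(config = cfg, performance = performance,
              summary = summarizeDatasets(performance),
              datasets = datasets, genome = genome)
  class(out) <- "ExperimentResult"
  out
}

# score one dataset: thresholds per model/method, detection, confusion
.score_dataset <- function(cfg, genome, reps, nullChr, bin, d) {
  thresholds <- list()
  rows <- list()
  for (m in cfg$models) {
    scale <- if (m %in% c("bmr", "bmr_bc")) "pip" else "p"
    res_list <- lapply(reps, function(x) x$results[[m]])
    methods <- if (scale == "pip") "nchr" else cfg$thresholdMethods
    for (meth in methods) {
      if (meth == "nchr") {
        thr_common <- nchrThreshold(res_list, nullChr = nullChr,
                                    binMarkers = bin, scale = scale)
        thresholds[[paste(m, meth, sep = "_")]] <- thr_common
      }
      acc <- fpr <- ppv <- rep(NA_real_, length(reps))
      flags <- NULL
      for (r in seq_along(reps)) {
        thr <- if (meth == "nchr") thr_common
               else bonferroniThreshold(reps[[r]]$meff)
        det <- detectQtl(res_list[[r]], reps[[r]]$arch, thr)
        flags <- cbind(flags, det$flags[, 1])
        part <- intervalPartition(reps[[r]]$arch, genome)
        cc <- confusionCounts(res_list[[r]], part, thr)
        pm <- perfMetrics(cc)
        acc[r] <- pm$accuracy
        fpr[r] <- pm$fpr
        ppv[r] <- pm$ppv
      }
      if (meth == "slide")
        thresholds[[paste(m, meth, sep = "_")]] <-
          bonferroniThreshold(reps[[length(reps)]]$meff)
      rows[[paste(m, meth, sep = "_")]] <- data.frame(
        model = toupper(m), method = toupper(meth),
        accuracy = mean(acc), power = mean(rowMeans(flags)),
        fpr = mean(fpr), ppv = mean(ppv, na.rm = TRUE))
    }
  }
  list(thresholds = thresholds, rows = rows)
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat(sprintf("ExperimentResult: %d dataset(s) x %d replicate(s), models: %s\n",
              x$config$nDatasets, x$config$nReplicates,
              paste(x$config$models, collapse = ", ")))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Render report tables and figures from an experiment result
#'
#' Writes the per-dataset and summary metric TSVs, Q-Q plots of the null
#' chromosome p-values per frequentist model, and a PCA scatter of the last
#' replicate's admixed genotypes, as static PDF/TSV outputs.
#'
#' @param result an \code{"ExperimentResult"} from [runExperiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
makeReport <- function(result, dir) {
  if (!is(result, "ExperimentResult") || !length(result$datasets))
    stop("empty or incomplete result store")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "summary_metrics.tsv")
  utils::write.table(result$summary, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "per_dataset_metrics.tsv")
  utils::write.table(result$performance, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  nullChr <- setdiff(seq_len(result$config$nChr),
                     sort(unique(result$config$targets$chr)))
  freq_models <- intersect(result$config$models,
                           c("sma", "sma_bc", "mlm", "mlm_bc"))
  for (m in freq_models) {
    p <- unlist(lapply(result$datasets[[1]]$replicates, function(rep) {
      res <- rep$results[[m]]
      res$p[res$chr %in% nullChr]
    }))
    qq <- qqData(p[!is.na(p)])
    f <- file.path(dir, sprintf("qq_%s.pdf", m))
    grDevices::pdf(f, width = 5, height = 5)
    plot(qq$data$expected, qq$data$observed, pch = 20, cex = 0.5,
         xlab = "expected -log10(p)", ylab = "observed -log10(p)",
         main = sprintf("%s null chromosomes (lambda = %.2f)",
                        toupper(m), qq$lambda))
    abline(0, 1, col = "grey50")
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
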