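#' Write PLINK text files (.ped / .map)
#'
#' The .ped family id is the individual's origin population label, parents are
#' 0 for pedigree founders, sex is 0, and the phenotype column is -9 unless
#' supplied. Genotypes are written as allele pairs coded 1/2 (allele 0 -> 1,
#' allele 1 -> 2). The .map holds chromosome, marker name, genetic distance in
#' cM and a pseudo base-pair position \code{round(cM * 1e6)}.
#'
#' @param pop a [Population-class].
#' @param panel global locus indices to export.
#' @param prefix output path prefix (writes \code{prefix.ped},
#'   \code{prefix.map}).
#' @param phen optional data.frame with \code{id} and \code{y}.
#' @return invisibly, the two file paths.
#' @export
writePlink <- function(pop, panel, prefix, phen = NULL) {
  map <- markerMap(pop@genome)[panel, , drop = FALSE]
  mapdf <- data.frame(chr = map$chr,
                      name = sprintf("M%d_%d", map$chr, map$locus),
                      cM = map$pos, bp = round(map$pos * 1e6))
  utils::write.table(mapdf, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ped <- pedigree(pop)
  rows <- ped[match(pop@ids, ped$id), ]
  y <- rep(-9, nInd(pop))
  if (!is.null(phen)) {
    m <- match(pop@ids, phen$id)
    y[!is.na(m)] <- phen$y[m[!is.na(m)]]
  }
  h <- pop@haplotypes[panel, , drop = FALSE]
  n <- nInd(pop)
  geno <- matrix("", n, 2 * nrow(mapdf))
  for (i in seq_len(n)) {
    a <- as.integer(h[, 2 * i - 1]) + 1L
    b <- as.integer(h[, 2 * i]) + 1L
    geno[i, ] <- as.character(rbind(a, b))
  }
  lead <- cbind(rows$pop, rows$id,
                ifelse(is.na(rows$sire), "0", rows$sire),
                ifelse(is.na(rows$dam), "0", rows$dam),
                "0", format(y, trim = TRUE))
  utils::write.table(cbind(lead, geno), paste0(prefix, ".ped"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Write a population snapshot
#'
#' Writes a columnar TSV (id, sire, dam, generation, population label, breed
#' fractions) and a small versioned binary haplotype container
#' (\code{prefix.hap}: magic "AQH1", locus and haplotype counts, then raw
#' 0/1 bytes in column order).
#'
#' @param pop a [Population-class].
#' @param prefix output path prefix.
#' @return invisibly, the file paths.
#' @export
writePopulationSnapshot <- function(pop, prefix) {
  ped <- pedigree(pop)
  rows <- ped[match(pop@ids, ped$id), ]
  df <- data.frame(id = rows$id, sire = rows$sire, dam = rows$dam,
                   generation = rows$generation, pop = rows$pop)
  bf <- breedFractions(pop)
  if (ncol(bf) > 0) df <- cbind(df, as.data.frame(bf))
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  hap <- paste0(prefix, ".hap")
  con <- file(hap, "wb")
  on.exit(close(con))
  writeChar("AQH1", con, 4, eos = NULL)
  writeBin(c(nrow(pop@haplotypes), ncol(pop@haplotypes)), con, size = 4)
  writeBin(as.vector(pop@haplotypes), con)
  invisible(c(tsv, hap))
}

#' Read a binary haplotype container written by [writePopulationSnapshot()]
#'
#' @param path path to the \code{.hap} file.
#' @return raw matrix (loci x haplotypes).
#' @export
readHaplotypes <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4)
  if (!identical(magic, "AQH1")) stop("not a versioned haplotype container")
  dims <- readBin(con, "integer", 2, size = 4)
  matrix(readBin(con, "raw", prod(dims)), nrow = dims[1])
}
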