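#' H1/H0 interval partition of the QTL chromosomes
#'
#' H1 windows are the closed +/- \code{window} cM intervals around each QTL
#' (truncated at chromosome ends). The remaining territory of the QTL-bearing
#' chromosomes is cut, per gap between (merged) QTL windows, into
#' \code{segment}-cM H0 segments from the left; a leftover shorter than
#' \code{segment} forms a final short segment and is scored normally.
#' Overlapping QTL windows merge for the H0 partition but keep separate H1
#' entries (each QTL is scored for power on its own window). Null chromosomes
#' are never part of the partition; they are reserved for thresholds.
#'
#' @param arch a [QTLArchitecture-class].
#' @param genome the [GenomeMap-class].
#' @param window H1 half-width in cM.
#' @param segment H0 segment length in cM.
#' @return list with data.frames \code{h1} (\code{qtl}, \code{chr},
#'   \code{start}, \code{end}) and \code{h0} (\code{chr}, \code{start},
#'   \code{end}).
#' @export
intervalPartition <- function(arch, genome, window = 2, segment = 4) {
  len <- chrLengths(genome)
  h1 <- data.frame(qtl = seq_along(arch@qtlIndex), chr = arch@chr,
                   start = pmax(arch@pos - window, 0),
                   end = pmin(arch@pos + window, len[arch@chr]))
  h0 <- list()
  for (c in sort(unique(arch@chr))) {
    win <- h1[h1$chr == c, , drop = FALSE]
    win <- win[order(win$start), , drop = FALSE]
    # merge overlapping/adjacent exclusion windows
    merged <- list()
    cur <- c(win$start[1], win$end[1])
    for (i in seq_len(nrow(win))[-1]) {
      if (win$start[i] <= cur[2]) cur[2] <- max(cur[2], win$end[i])
      else { merged[[length(merged) + 1]] <- cur; cur <- c(win$start[i], win$end[i]) }
    }
    merged[[length(merged) + 1]] <- cur
    gaps <- rbind(
      if (merged[[1]][1] > 0) c(0, merged[[1]][1]),
      if (length(merged) > 1)
        do.call(rbind, lapply(seq_len(length(merged) - 1), function(i)
          c(merged[[i]][2], merged[[i + 1]][1]))),
      if (merged[[length(merged)]][2] < len[c]) c(merged[[length(merged)]][2], len[c])
    )
    if (is.null(gaps)) next
    for (g in seq_len(nrow(gaps))) {
      a <- gaps[g, 1]; b <- gaps[g, 2]
      cuts <- seq(a, b, by = segment)
      if (cuts[length(cuts)] < b) cuts <- c(cuts, b)
      for (s in seq_len(length(cuts) - 1))
        h0[[length(h0) + 1]] <- data.frame(chr = c, start = cuts[s],
                                           end = cuts[s + 1])
    }
  }
  h0 <- if (length(h0)) do.call(rbind, h0) else
    data.frame(chr = integer(0), start = numeric(0), end = numeric(0))
  # invariant: H0 segments lie wholly outside every H1 window
  for (i in seq_len(nrow(h0))) {
    ov <- h1$chr == h0$chr[i] & h1$start < h0$end[i] & h1$end > h0$start[i]
    if (any(ov)) stop("internal error: H0 segment overlaps an H1 window")
  }
  list(h1 = h1, h0 = h0)
}

.is_significant <- function(res, threshold) {
  if (threshold$scale == "p") !is.na(res$p) & res$p < threshold$value
  else !is.na(res$pip) & res$pip > threshold$value
}

#' Declare QTL detections and compute power
#'
#' A QTL is declared detected in a replicate if any marker within the closed
#' +/- \code{window} cM interval around it is significant at the supplied
#' threshold (p below the 5 percent threshold, or PIP above the 95 percent
#' threshold). Power per QTL is the detected fraction over replicates; the
#' reported power is the mean over QTL.
#'
#' @param results scan data.frame or list of them (one per replicate), with
#'   \code{chr}, \code{pos} and \code{p}/\code{pip} columns.
#' @param arch a [QTLArchitecture-class].
#' @param threshold a \code{"ThresholdSet"}.
#' @param window detection half-width in cM.
#' @return list with \code{flags} (QTL x replicate logical matrix),
#'   \code{powerPerQtl}, \code{power}.
#' @export
detectQtl <- function(results, arch, threshold, window = 2) {
  if (is.data.frame(results)) results <- list(results)
  nq <- length(arch@qtlIndex)
  flags <- matrix(FALSE, nq, length(results))
  for (r in seq_along(results)) {
    res <- results[[r]]
    sig <- .is_significant(res, threshold)
    for (q in seq_len(nq)) {
      inwin <- res$chr == arch@chr[q] &
        res$pos >= arch@pos[q] - window & res$pos <= arch@pos[q] + window
      flags[q, r] <- any(sig & inwin)
    }
  }
  ppq <- rowMeans(flags)
  list(flags = flags, powerPerQtl = ppq, power = mean(ppq))
}

#' Interval-level confusion counts for one replicate
#'
#' Scores each H1 window and H0 segment of the partition: an H1 window with at
#' least one significant marker is a true positive (else false negative); an
#' H0 segment with at least one significant marker is a false positive (else
#' true negative). Interval bounds are closed.
#'
#' @param res one scan data.frame.
#' @param partition from [intervalPartition()].
#' @param threshold a \code{"ThresholdSet"}.
#' @return named integer vector \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusionCounts <- function(res, partition, threshold) {
  sig <- .is_significant(res, threshold)
  hit <- function(iv) {
    any(sig & res$chr == iv$chr & res$pos >= iv$start & res$pos <= iv$end)
  }
  h1hit <- vapply(seq_len(nrow(partition$h1)), function(i)
    hit(partition$h1[i, ]), TRUE)
  h0hit <- vapply(seq_len(nrow(partition$h0)), function(i)
    hit(partition$h0[i, ]), TRUE)
  c(TP = sum(h1hit), FP = sum(h0hit), TN = sum(!h0hit), FN = sum(!h1hit))
}

#' Performance metrics from confusion counts
#'
#' @param counts named vector with \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @return data.frame with \code{accuracy}, \code{fpr}, \code{ppv} (NA when
#'   TP + FP = 0).
#' @export
perfMetrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  data.frame(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' Average per-dataset metrics across datasets
#'
#' Means and standard errors of the per-dataset performance measures, by
#' model and threshold method. With a single dataset the SE is reported
#' missing.
#'
#' @param perDataset data.frame with columns \code{dataset}, \code{model},
#'   \code{method}, \code{accuracy}, \code{power}, \code{fpr}, \code{ppv}.
#' @return data.frame with one row per (model, method) and mean/se columns.
#' @export
summarizeDatasets <- function(perDataset) {
  stopifnot(nrow(perDataset) >= 1)
  metrics <- c("accuracy", "power", "fpr", "ppv")
  groups <- unique(perDataset[, c("model", "method"), drop = FALSE])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- perDataset[perDataset$model == groups$model[g] &
                        perDataset$method == groups$method[g], , drop = FALSE]
    out <- data.frame(model = groups$model[g], method = groups$method[g],
                      n_datasets = nrow(sub))
    for (m in metrics) {
      v <- sub[[m]]
      out[[m]] <- mean(v, na.rm = TRUE)
      out[[paste0(m, "_se")]] <- if (sum(!is.na(v)) > 1)
        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
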