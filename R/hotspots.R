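#' Partition the genome into fixed-width cM bins
#'
#' Tiles each chromosome of a genetic map with contiguous bins of
#' `widthCm` centimorgans (the last bin of a chromosome may be shorter).
#' The number of bins is the sum over chromosomes of
#' `ceiling(span / widthCm)`.
#'
#' @param map a [GeneticMap-class].
#' @param widthCm bin width in cM (default 5).
#' @return data.frame of class `"HotspotBins"`: `chrom`, `start_cM`,
#'   `end_cM`, `bin` (index).
#' @export
binGenome <- function(map, widthCm = 5) {
  spans <- chromosomeSpans(map)
  if (all(spans <= widthCm)) stop("map must span more than one bin width")
  out <- do.call(rbind, lapply(names(spans), function(cc) {
    n <- ceiling(spans[[cc]] / widthCm)
    start <- (seq_len(n) - 1) * widthCm
    data.frame(chrom = cc, start_cM = start,
               end_cM = pmin(start + widthCm, spans[[cc]]))
  }))
  out$bin <- seq_len(nrow(out))
  class(out) <- c("HotspotBins", "data.frame")
  attr(out, "widthCm") <- widthCm
  out
}

#' Count significant trans linkages per genome bin
#'
#' Assigns each significant eQTL peak (FDR at or below `fdrMax`) to the
#' bin containing its peak cM position, after removing cis linkages: a
#' linkage is cis when the transcribed gene lies on the peak chromosome
#' within the peak's confidence interval extended by `cisPadBp` on both
#' sides. Peaks whose gene has no coordinates are excluded with a message.
#'
#' @param peaks peak table from [transScan()] (optionally with an `fdr`
#'   column from [transPermutationFdr()]); needs columns `gene`,
#'   `gene_chrom`, `gene_pos`, `chrom`, `cM` (peak cM; computed from a
#'   map via `map` if absent), `ci_lo_pos`, `ci_hi_pos`, `fdr`,
#'   `cell_type`.
#' @param bins from [binGenome()].
#' @param fdrMax significance threshold on the FDR column (default 0.1).
#' @param cisPadBp cis exclusion pad in bp (default 1e6).
#' @param map optional [GeneticMap-class] to interpolate peak cM positions
#'   when `peaks$cM` is missing.
#' @return list of class `"LinkageCounts"`: `bins` (the bin table with a
#'   `count` column per cell type in wide data.frame `counts`), `assigned`
#'   (the retained peak rows with their bin).
#' @export
countTransLinkages <- function(peaks, bins, fdrMax = 0.1, cisPadBp = 1e6,
                               map = NULL) {
  stopifnot(inherits(bins, "HotspotBins"))
  if (is.null(peaks$cM)) {
    if (is.null(map)) stop("peaks lack cM positions; supply a map")
    peaks$cM <- interpolateMap(map, peaks$chrom, peaks$pos)
  }
  ok <- !is.na(peaks$gene_pos) & !is.na(peaks$gene_chrom)
  if (any(!ok))
    message("countTransLinkages: excluding ", sum(!ok),
            " peaks whose gene has no coordinates")
  peaks <- peaks[ok, , drop = FALSE]
  sig <- peaks$fdr <= fdrMax
  isCis <- peaks$gene_chrom == peaks$chrom &
    peaks$gene_pos >= peaks$ci_lo_pos - cisPadBp &
    peaks$gene_pos <= peaks$ci_hi_pos + cisPadBp
  keep <- peaks[sig & !isCis, , drop = FALSE]
  # bin containing the peak cM position (end-inclusive on the last bin)
  keep$bin <- vapply(seq_len(nrow(keep)), function(i) {
    b <- bins[bins$chrom == keep$chrom[i], ]
    hit <- which(keep$cM[i] >= b$start_cM &
                   (keep$cM[i] < b$end_cM |
                      (keep$cM[i] == b$end_cM & b$end_cM == max(b$end_cM))))
    if (length(hit)) b$bin[hit[1]] else NA_integer_
  }, integer(1))
  keep <- keep[!is.na(keep$bin), , drop = FALSE]
  types <- unique(peaks$cell_type)
  counts <- matrix(0L, nrow(bins), length(types),
                   dimnames = list(NULL, types))
  if (nrow(keep)) {
    tab <- table(factor(keep$bin, levels = bins$bin), keep$cell_type)
    counts[, colnames(tab)] <- as.matrix(tab)
  }
  structure(list(bins = bins, counts = counts, assigned = keep),
            class = "LinkageCounts")
}

#' @export
print.LinkageCounts <- function(x, ...) {
  cat("LinkageCounts:", nrow(x$bins), "bins x", ncol(x$counts),
      "cell types;", sum(x$counts), "trans linkages\n")
  invisible(x)
}

#' Detect trans-eQTL hotspots
#'
#' Per cell type, a bin holds an excess of trans linkages when its count
#' exceeds the upper tail of a Poisson distribution whose mean is that
#' cell type's average count per bin, at a Bonferroni-corrected level
#' `alpha / nBins`. Runs of adjacent significant bins are reduced to
#' local maxima: a significant bin is a peak when its count is strictly
#' greater than both neighbours' counts (one-sided at chromosome ends;
#' ties broken leftmost).
#'
#' @param linkages a `"LinkageCounts"` from [countTransLinkages()].
#' @param alpha genome-wide significance level (default 0.05).
#' @return data.frame with one row per hotspot: `cell_type`, `bin`,
#'   `chrom`, `start_cM`, `end_cM`, `count`, `p`, `threshold`.
#' @export
detectHotspots <- function(linkages, alpha = 0.05) {
  stopifnot(inherits(linkages, "LinkageCounts"))
  bins <- linkages$bins
  nBins <- nrow(bins)
  thr <- alpha / nBins
  out <- list()
  for (ct in colnames(linkages$counts)) {
    cnt <- linkages$counts[, ct]
    lambda <- mean(cnt)
    if (lambda == 0) {
      if (all(cnt == 0)) next
      # degenerate: nonzero counts but zero mean cannot occur; guard anyway
      lambda <- min(colMeans(linkages$counts)[colMeans(linkages$counts) >
                                                0])
      message("detectHotspots: zero mean with nonzero counts for ", ct,
              "; substituting smallest positive mean")
    }
    p <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
    sig <- p < thr
    if (!any(sig)) next
    # local maxima at the level of runs of equal counts within a
    # chromosome; a peak run keeps its leftmost significant bin
    for (cc in unique(bins$chrom)) {
      idx <- which(bins$chrom == cc)
      v <- cnt[idx]
      runEnd <- c(which(diff(v) != 0), length(v))
      runStart <- c(1, runEnd[-length(runEnd)] + 1)
      for (r in seq_along(runStart)) {
        lo <- runStart[r]; hi <- runEnd[r]
        upLeft <- r == 1 || v[runStart[r - 1]] < v[lo]
        upRight <- r == length(runStart) || v[runStart[r + 1]] < v[lo]
        if (!(upLeft && upRight)) next
        cand <- idx[lo:hi][sig[idx[lo:hi]]]
        if (!length(cand)) next
        i <- cand[1]
        out[[length(out) + 1]] <- data.frame(
          cell_type = ct, bin = bins$bin[i], chrom = cc,
          start_cM = bins$start_cM[i], end_cM = bins$end_cM[i],
          count = cnt[i], p = p[i], threshold = thr)
      }
    }
  }
  if (!length(out))
    return(data.frame(cell_type = character(), bin = integer(),
                      chrom = character(), start_cM = numeric(),
                      end_cM = numeric(), count = integer(),
                      p = numeric(), threshold = numeric()))
  do.call(rbind, out)
}
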