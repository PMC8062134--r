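#' Permute cell identities within batches
#'
#' Returns a permutation of cell indices in which cells are shuffled only
#' among the cells of their own library batch, as used to break the
#' genotype-expression link while preserving batch structure. The same
#' permutation is applied to all transcripts of a permutation instance.
#'
#' When `groups` is supplied (e.g. the inferred individual of origin of
#' each cell), cells of one group are kept together and the group blocks
#' are shuffled within the batch, so all cells of an individual receive
#' genotypes from the same run of foreign cells; without it every cell is
#' treated as its own segregant.
#'
#' @param batch batch label per cell.
#' @param seed RNG seed.
#' @param groups optional segregant/individual label per cell.
#' @return integer permutation vector of `length(batch)`.
#' @export
permuteWithinBatch <- function(batch, seed = 1, groups = NULL) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  idx <- seq_along(batch)
  for (b in unique(batch)) {
    pos <- which(batch == b)
    if (is.null(groups)) {
      idx[pos] <- pos[sample.int(length(pos))]
    } else {
      g <- groups[pos]
      blocks <- split(pos, factor(g, levels = unique(g)))
      idx[pos] <- unlist(blocks[sample.int(length(blocks))],
                         use.names = FALSE)
    }
  }
  idx
}

#' Build an FDR curve from observed and permuted peak LOD scores
#'
#' For LOD thresholds from 0.1 to 0.1 plus the maximum observed LOD in
#' steps of 0.01, the expected count is the mean over permutations of the
#' number of transcripts whose (permuted) peak LOD exceeds the threshold,
#' and the observed count is the same quantity in the real data. The FDR
#' at a threshold is expected/observed, clipped to [0, 1] and monotonized
#' (non-increasing in the threshold, via a running minimum). Thresholds
#' with zero observed count leave the FDR undefined; interpolation is
#' restricted to the supported range and clamps outside it.
#'
#' @param observed per-transcript observed peak LOD scores.
#' @param permuted matrix of permuted peak LODs, transcripts x
#'   permutations.
#' @return object of class `"FdrCurve"`: list with `grid`, `expected`,
#'   `observed`, `fdr` (monotonized), and `adjust(lod)`, a function
#'   mapping peak LODs to FDR-adjusted p-values by linear interpolation.
#' @export
fdrFromPermutations <- function(observed, permuted) {
  permuted <- as.matrix(permuted)
  stopifnot(nrow(permuted) == length(observed))
  grid <- seq(0.1, max(observed) + 0.1, by = 0.01)
  obsCount <- vapply(grid, function(t) sum(observed > t), numeric(1))
  expCount <- vapply(grid, function(t) mean(colSums(permuted > t)),
                     numeric(1))
  fdrRaw <- ifelse(obsCount > 0, pmin(pmax(expCount / obsCount, 0), 1),
                   NA_real_)
  sup <- !is.na(fdrRaw)
  fdr <- fdrRaw
  fdr[sup] <- cummin(fdrRaw[sup])
  g <- grid[sup]; f <- fdr[sup]
  adjust <- if (sum(sup) >= 2) {
    function(lod) stats::approx(g, f, xout = lod, rule = 2)$y
  } else if (sum(sup) == 1) {
    function(lod) rep(f, length(lod))
  } else {
    function(lod) rep(1, length(lod))  # nothing observed anywhere
  }
  structure(list(grid = grid, expected = expCount, observed = obsCount,
                 fdr = fdr, adjust = adjust),
            class = "FdrCurve")
}

#' @export
print.FdrCurve <- function(x, ...) {
  cat("FdrCurve:", length(x$grid), "thresholds from", x$grid[1], "to",
      x$grid[length(x$grid)], "\n")
  invisible(x)
}

#' Permutation FDR for a cis scan
#'
#' Reruns the cis likelihood-ratio test of every transcript at its closest
#' marker under permutations of cell identity within batch (the reduced
#' model does not involve the genotype, so its likelihood is reused from
#' the observed fit), builds the [fdrFromPermutations()] curve, and
#' attaches an `fdr` column to the scan result.
#'
#' @param sce,markers,cellType,minCells as in [cisScan()].
#' @param cisResult result of [cisScan()] on the same data.
#' @param nPerm number of permutations (default 10).
#' @param seed RNG seed; permutation `i` uses `seed + i`.
#' @param groups optional per-cell segregant labels, permuted as blocks
#'   (see [permuteWithinBatch()]).
#' @return list with `result` (the cis table plus an `fdr` column) and
#'   `curve` (the `"FdrCurve"`).
#' @export
cisPermutationFdr <- function(sce, markers, cisResult, cellType = NULL,
                              minCells = 20, nPerm = 10, seed = 1,
                              groups = NULL) {
  prep <- .scanPrep(sce, markers, cellType, minCells)
  stopifnot(identical(prep$genes, cisResult$gene))
  batch <- as.data.frame(
    SummarizedExperiment::colData(sce))$batch
  if (!is.null(cellType))
    batch <- batch[SummarizedExperiment::colData(sce)$cell_type ==
                     cellType]
  nG <- length(prep$genes)
  permLod <- matrix(0, nG, nPerm)
  # reduced-model likelihoods are genotype-free: refit once per gene
  redLik <- numeric(nG)
  for (k in seq_len(nG)) {
    y <- prep$Y[prep$genes[k], ]
    redLik[k] <- fitNbGlm(y, prep$X0, theta = cisResult$theta[k])$logLik
  }
  for (i in seq_len(nPerm)) {
    pidx <- permuteWithinBatch(batch, seed = seed + i, groups = groups)
    Dp <- prep$D[pidx, , drop = FALSE]
    for (k in seq_len(nG)) {
      y <- prep$Y[prep$genes[k], ]
      Xf <- cbind(prep$X0, dosage = Dp[, prep$closest[k]])
      full <- fitNbGlm(y, Xf, theta = cisResult$theta[k])
      permLod[k, i] <- lrtLod(full$logLik, redLik[k], slack = 1e-3)$lod
    }
  }
  curve <- fdrFromPermutations(cisResult$lod, permLod)
  cisResult$fdr <- curve$adjust(cisResult$lod)
  list(result = cisResult, curve = curve)
}

#' Permutation FDR for a genome-wide (trans) scan
#'
#' For each chromosome, records each transcript's maximum permuted LOD
#' across the chromosome's markers under within-batch permutations of cell
#' identity, builds a per-chromosome [fdrFromPermutations()] curve from
#' the observed per-transcript chromosome maxima, and attaches an `fdr`
#' column to the peak table.
#'
#' @param sce,markers,cellType,minCells as in [transScan()].
#' @param transResult result of [transScan()] on the same data.
#' @param nPerm number of permutations (default 10).
#' @param seed RNG seed.
#' @param groups optional per-cell segregant labels, permuted as blocks
#'   (see [permuteWithinBatch()]).
#' @return list with `peaks` (peak table plus `fdr`) and `curves` (named
#'   list of `"FdrCurve"` per chromosome).
#' @export
transPermutationFdr <- function(sce, markers, transResult,
                                cellType = NULL, minCells = 20,
                                nPerm = 10, seed = 1, groups = NULL) {
  prep <- .scanPrep(sce, markers, cellType, minCells)
  batch <- as.data.frame(SummarizedExperiment::colData(sce))$batch
  if (!is.null(cellType))
    batch <- batch[SummarizedExperiment::colData(sce)$cell_type ==
                     cellType]
  peaks <- transResult$peaks
  nG <- length(prep$genes)
  thetaOf <- peaks$theta[match(prep$genes, peaks$gene)]
  redLik <- numeric(nG)
  redBeta <- vector("list", nG)
  for (k in seq_len(nG)) {
    y <- prep$Y[prep$genes[k], ]
    red <- fitNbGlm(y, prep$X0, theta = thetaOf[k])
    redLik[k] <- red$logLik
    redBeta[[k]] <- red$beta
  }
  chroms <- unique(markers$info$chrom)
  curves <- list()
  peaks$fdr <- NA_real_
  for (cc in chroms) {
    mIdx <- which(markers$info$chrom == cc)
    permMax <- matrix(0, nG, nPerm)
    for (i in seq_len(nPerm)) {
      pidx <- permuteWithinBatch(batch, seed = seed + i, groups = groups)
      Dp <- prep$D[pidx, mIdx, drop = FALSE]
      for (k in seq_len(nG)) {
        y <- prep$Y[prep$genes[k], ]
        best <- 0
        for (j in seq_along(mIdx)) {
          Xf <- cbind(prep$X0, dosage = Dp[, j])
          full <- fitNbGlm(y, Xf, theta = thetaOf[k],
                           beta = c(redBeta[[k]], dosage = 0))
          best <- max(best,
                      lrtLod(full$logLik, redLik[k], slack = 1e-3)$lod)
        }
        permMax[k, i] <- best
      }
    }
    rows <- which(peaks$chrom == cc)
    obs <- peaks$lod[rows][match(prep$genes, peaks$gene[rows])]
    curve <- fdrFromPermutations(obs, permMax)
    curves[[cc]] <- curve
    peaks$fdr[rows] <- curve$adjust(peaks$lod[rows])
  }
  list(peaks = peaks, curves = curves)
}
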