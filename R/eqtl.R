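#' Genes expressed in a cell type
#'
#' A transcript is considered expressed in a cell type when it has a
#' non-zero UMI count in at least `minCells` cells of that type.
#'
#' @param counts counts matrix (genes x cells) or a
#'   [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment].
#' @param cellType if `counts` is a SingleCellExperiment, restrict to the
#'   cells with this `cell_type`; `NULL` uses all columns.
#' @param minCells threshold (default 20).
#' @return character vector of gene names (or row indices if unnamed).
#' @export
filterExpressed <- function(counts, cellType = NULL, minCells = 20) {
  if (is(counts, "SummarizedExperiment")) {
    if (!is.null(cellType)) {
      keep <- SummarizedExperiment::colData(counts)$cell_type == cellType
      if (!any(keep)) stop("cell type ", cellType, " not present")
      counts <- counts[, keep]
    }
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  nPos <- Matrix::rowSums(counts > 0)
  keep <- which(nPos >= minCells)
  if (!length(keep))
    message("filterExpressed: no gene passes the ", minCells,
            "-cell threshold")
  if (!is.null(rownames(counts))) rownames(counts)[keep] else keep
}

# population-variance standardization (divide by n, not n-1)
.standardize <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  sweep(sweep(x, 2, m), 2, s, "/")
}

#' Prune markers in very high LD and standardize dosages
#'
#' Transposes a sites-x-cells dosage matrix to cells x markers,
#' standardizes each marker to mean 0 and (population) variance 1, and
#' prunes markers by greedy left-to-right retention within each
#' chromosome: a marker is dropped when its Pearson correlation with the
#' last retained marker exceeds `rMax`. At the default `rMax = 0.9999`
#' this is approximately equivalent to keeping markers spaced a few cM
#' apart, depending on depth. Constant-dosage markers cannot be
#' standardized and are dropped with a message.
#'
#' @param dosageMatrix sites x cells dosage matrix, or a
#'   [GenotypePosteriors-class].
#' @param sites data.frame with `chrom`, `pos` per site (taken from the
#'   posteriors object when one is supplied).
#' @param rMax LD pruning threshold (default 0.9999).
#' @param map optional [GeneticMap-class]; when given, marker cM positions
#'   are added to the marker table.
#' @return list of class `"MarkerDosage"`: `dosage` (cells x markers,
#'   standardized), `info` (data.frame `site`, `chrom`, `pos`, optionally
#'   `cM`).
#' @export
pruneMarkers <- function(dosageMatrix, sites = NULL, rMax = 0.9999,
                         map = NULL) {
  if (is(dosageMatrix, "GenotypePosteriors")) {
    sites <- siteInfo(dosageMatrix)
    dosageMatrix <- dosage(dosageMatrix)
  }
  stopifnot(!is.null(sites), nrow(sites) == nrow(dosageMatrix))
  X <- t(as.matrix(dosageMatrix))          # cells x sites
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    message("pruneMarkers: dropping ", sum(v == 0),
            " constant-dosage markers")
  }
  keep <- logical(ncol(X))
  for (cc in unique(sites$chrom)) {
    idx <- which(sites$chrom == cc & v > 0)
    last <- NA_integer_
    for (j in idx) {
      if (is.na(last) ||
          abs(stats::cor(X[, j], X[, last])) <= rMax) {
        keep[j] <- TRUE
        last <- j
      }
    }
  }
  kept <- which(keep)
  if (!length(kept)) stop("no markers left after pruning")
  info <- data.frame(site = kept, chrom = sites$chrom[kept],
                     pos = sites$pos[kept])
  if (!is.null(map)) info$cM <- interpolateMap(map, info$chrom, info$pos)
  structure(list(dosage = .standardize(X[, kept, drop = FALSE]),
                 info = info, rMax = rMax),
            class = "MarkerDosage")
}

#' @export
print.MarkerDosage <- function(x, ...) {
  cat("MarkerDosage:", nrow(x$dosage), "cells x", ncol(x$dosage),
      "markers (r_max =", x$rMax, ")\n")
  invisible(x)
}

# base covariate matrix for a set of cells: intercept, log total UMIs,
# batch indicators (dropped when a single batch is present)
.baseModelMatrix <- function(cd) {
  X <- cbind(intercept = 1, log_total = cd$log_total)
  b <- droplevels(factor(cd$batch))
  if (nlevels(b) > 1) {
    B <- stats::model.matrix(~b)[, -1, drop = FALSE]
    colnames(B) <- paste0("batch", levels(b)[-1])
    X <- cbind(X, B)
  }
  X
}

# Wald standard error of coefficient j at the IRLS solution
.coefSe <- function(X, mu, theta, j) {
  w <- mu * theta / (theta + mu)
  XtWX <- crossprod(X, X * w)
  sqrt(solve(XtWX)[j, j])
}

#' Map cis eQTLs in one cell type
#'
#' For each expressed transcript, fits the negative-binomial GLM
#' `mu = exp(b_i + X_t b_t + X_b b_b + X_c b_c)` where `X_c` is the
#' standardized dosage of the closest pruned marker to the transcript, and
#' tests `b_c = 0` by a likelihood-ratio test against the model without
#' `X_c`. The overdispersion `theta` is estimated once per transcript from
#' the full cis model and reused for the reduced fit (and by
#' [transScan()]); unmodelled factors are thereby absorbed into the
#' overdispersion, which is conservative.
#'
#' @param sce a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with a `counts` assay, `colData` columns `batch`, `log_total`,
#'   `cell_type`, and gene coordinates (`chrom`, `pos`) in `rowData`.
#' @param markers a `"MarkerDosage"` from [pruneMarkers()] (rows aligned
#'   with the columns of `sce`).
#' @param cellType cell type to map in; `NULL` uses all cells.
#' @param minCells expression filter threshold (default 20).
#' @return data.frame with one row per mapped transcript: gene and marker
#'   coordinates, `effect` (coefficient of the standardized dosage), `se`,
#'   `theta`, `lod`, `p`. Genes without a marker on their chromosome are
#'   skipped with a message.
#' @export
cisScan <- function(sce, markers, cellType = NULL, minCells = 20) {
  prep <- .scanPrep(sce, markers, cellType, minCells)
  if (!length(prep$genes)) return(.emptyScan())
  res <- vector("list", length(prep$genes))
  for (k in seq_along(prep$genes)) {
    g <- prep$genes[k]
    j <- prep$closest[k]
    y <- prep$Y[g, ]
    Xc <- prep$D[, j]
    Xfull <- cbind(prep$X0, dosage = Xc)
    full <- fitNbGlm(y, Xfull)
    red <- fitNbGlm(y, prep$X0, theta = full$theta)
    lt <- lrtLod(full$logLik, red$logLik)
    res[[k]] <- data.frame(
      gene = g, cell_type = prep$label,
      gene_chrom = prep$geneInfo$chrom[k], gene_pos = prep$geneInfo$pos[k],
      marker = j, chrom = markers$info$chrom[j],
      pos = markers$info$pos[j],
      effect = unname(full$beta["dosage"]),
      se = .coefSe(Xfull, full$mu, full$theta, ncol(Xfull)),
      theta = full$theta, lod = lt$lod, p = lt$p
    )
  }
  do.call(rbind, res)
}

.emptyScan <- function() data.frame()

# shared setup for cis/trans scans
.scanPrep <- function(sce, markers, cellType, minCells) {
  stopifnot(inherits(markers, "MarkerDosage"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  keep <- if (is.null(cellType)) rep(TRUE, ncol(sce))
          else cd$cell_type == cellType
  if (!any(keep)) stop("cell type ", cellType, " not present")
  Y <- as.matrix(SummarizedExperiment::assay(sce, "counts"))[, keep,
                                                             drop = FALSE]
  D <- markers$dosage[keep, , drop = FALSE]
  # re-standardize within the mapped cell subset
  D <- .standardize(D)
  X0 <- .baseModelMatrix(cd[keep, , drop = FALSE])
  genes <- filterExpressed(Y, minCells = minCells)
  gi <- as.data.frame(SummarizedExperiment::rowData(sce))
  gi <- gi[match(genes, gi$gene), , drop = FALSE]
  closest <- vapply(seq_along(genes), function(k) {
    onChrom <- which(markers$info$chrom == gi$chrom[k])
    if (!length(onChrom)) return(NA_integer_)
    onChrom[which.min(abs(markers$info$pos[onChrom] - gi$pos[k]))]
  }, integer(1))
  if (any(is.na(closest))) {
    message("scan: skipping ", sum(is.na(closest)),
            " genes with no marker on their chromosome")
    keepG <- !is.na(closest)
    genes <- genes[keepG]; gi <- gi[keepG, , drop = FALSE]
    closest <- closest[keepG]
  }
  list(Y = Y, D = D, X0 = X0, genes = genes, geneInfo = gi,
       closest = closest,
       label = if (is.null(cellType)) "all" else cellType)
}

#' Genome-wide (trans) eQTL scan in one cell type
#'
#' Fits the negative-binomial GLM at every pruned marker for every
#' expressed transcript, reusing each transcript's `theta` from its cis
#' fit (estimated here when not supplied). Per transcript and chromosome,
#' the peak is the marker with the highest LOD (ties broken leftmost) and
#' an approximate 95% confidence interval is derived by the 1.5-LOD-drop
#' rule.
#'
#' @inheritParams cisScan
#' @param thetas optional named vector of per-transcript overdispersions
#'   (as returned in the `theta` column of [cisScan()]).
#' @param drop LOD drop for confidence intervals (default 1.5).
#' @return list with `peaks` (data.frame: one row per transcript per
#'   chromosome, with peak marker, LOD, effect, CI marker indices and bp)
#'   and `lod` (transcripts x markers LOD matrix).
#' @export
transScan <- function(sce, markers, cellType = NULL, thetas = NULL,
                      minCells = 20, drop = 1.5) {
  prep <- .scanPrep(sce, markers, cellType, minCells)
  nM <- ncol(prep$D)
  nG <- length(prep$genes)
  lodMat <- matrix(0, nG, nM, dimnames = list(prep$genes, NULL))
  effMat <- matrix(0, nG, nM)
  peaks <- vector("list", nG)
  chroms <- markers$info$chrom
  for (k in seq_len(nG)) {
    g <- prep$genes[k]
    y <- prep$Y[g, ]
    th <- if (!is.null(thetas) && g %in% names(thetas)) thetas[[g]] else {
      Xc <- cbind(prep$X0, dosage = prep$D[, prep$closest[k]])
      fitNbGlm(y, Xc)$theta
    }
    red <- fitNbGlm(y, prep$X0, theta = th)
    for (j in seq_len(nM)) {
      Xf <- cbind(prep$X0, dosage = prep$D[, j])
      full <- fitNbGlm(y, Xf, theta = th,
                       beta = c(red$beta, dosage = 0))
      lt <- lrtLod(full$logLik, red$logLik)
      lodMat[k, j] <- lt$lod
      effMat[k, j] <- unname(full$beta["dosage"])
    }
    rows <- lapply(unique(chroms), function(cc) {
      idx <- which(chroms == cc)
      lodC <- lodMat[k, idx]
      pk <- idx[which.max(lodC)]          # which.max: leftmost on ties
      ci <- lodDropCi(lodC, drop = drop)
      data.frame(gene = g, cell_type = prep$label,
                 gene_chrom = prep$geneInfo$chrom[k],
                 gene_pos = prep$geneInfo$pos[k],
                 chrom = cc, marker = pk,
                 pos = markers$info$pos[pk],
                 effect = effMat[k, pk],
                 theta = th, lod = lodMat[k, pk],
                 p = stats::pchisq(lodMat[k, pk] * 2 * log(10), df = 1,
                                   lower.tail = FALSE),
                 ci_lo_marker = idx[ci[1]], ci_hi_marker = idx[ci[2]],
                 ci_lo_pos = markers$info$pos[idx[ci[1]]],
                 ci_hi_pos = markers$info$pos[idx[ci[2]]])
    })
    peaks[[k]] <- do.call(rbind, rows)
  }
  list(peaks = do.call(rbind, peaks), lod = lodMat)
}

#' 1.5-LOD-drop confidence interval
#'
#' Starting at the peak (leftmost on ties), expands left and right over
#' the contiguous run of markers whose LOD stays within `drop` of the
#' peak; the interval is clamped at the chromosome ends. On a flat curve
#' the interval spans the whole chromosome; an isolated spike yields a
#' single-marker interval.
#'
#' @param lod LOD scores along one chromosome, in marker order.
#' @param drop LOD units below the peak still inside the interval
#'   (default 1.5, an approximate 95% interval).
#' @return integer vector `c(lo, hi)` of marker indices.
#' @export
lodDropCi <- function(lod, drop = 1.5) {
  stopifnot(length(lod) >= 1)
  pk <- which.max(lod)
  thr <- lod[pk] - drop
  lo <- pk
  while (lo > 1 && lod[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < length(lod) && lod[hi + 1] >= thr) hi <- hi + 1
  c(lo, hi)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone), as used for the single-neuron
#' subtype cis scans where cell numbers are too small for permutation.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' LOD score from a squared correlation
#'
#' Transforms the squared Pearson correlation between a transcript and a
#' marker into a LOD score, `-n ln(1 - R^2) / (2 ln 10)` — the Gaussian
#' nested-model likelihood-ratio form used for bulk (whole-organism)
#' eQTL data.
#'
#' @param r2 squared correlation, in [0, 1).
#' @param n sample size (>= 2).
#' @return LOD score.
#' @examples
#' lodFromCorrelation(0.5, 100)  # ~15.05
#' @export
lodFromCorrelation <- function(r2, n) {
  stopifnot(n >= 2)
  if (any(r2 < 0 | r2 >= 1)) stop("need 0 <= R^2 < 1")
  -n * log(1 - r2) / (2 * log(10))
}

#' Stouffer's weighted-Z combination
#'
#' Combines standardized effects (Z scores) across cell types:
#' \eqn{Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}}.
#'
#' @param z standardized effects.
#' @param weights positive weights (default equal).
#' @return combined Z.
#' @export
stoufferCombine <- function(z, weights = rep(1, length(z))) {
  stopifnot(length(z) >= 1, length(weights) == length(z),
            all(weights > 0))
  sum(weights * z) / sqrt(sum(weights^2))
}

#' Effect-direction concordance between two mappings
#'
#' Compares the sign of each transcript's effect in two mappings (e.g. a
#' single-neuron subtype versus all other neurons) and tests the
#' concordant/discordant split against chance with a two-sided exact
#' binomial test. Transcripts with a zero or missing effect in either
#' mapping are excluded with a message.
#'
#' @param effectsA,effectsB paired effect estimates.
#' @return list with `nSame`, `nOpposite`, `p`.
#' @export
directionConcordance <- function(effectsA, effectsB) {
  stopifnot(length(effectsA) == length(effectsB))
  ok <- is.finite(effectsA) & is.finite(effectsB) &
    effectsA != 0 & effectsB != 0
  if (any(!ok))
    message("directionConcordance: excluding ", sum(!ok),
            " pairs with zero or missing effects")
  sA <- sign(effectsA[ok]); sB <- sign(effectsB[ok])
  nSame <- sum(sA == sB)
  n <- length(sA)
  list(nSame = nSame, nOpposite = n - nSame,
       p = stats::binom.test(nSame, n, 0.5)$p.value)
}
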