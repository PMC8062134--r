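#' Plant an eQTL architecture into a simulated cross
#'
#' Draws per-gene expression parameters (baseline log mean, negative-
#' binomial overdispersion theta, batch and cell-type log-scale offsets)
#' and plants cis and trans genetic effects. A cis effect links a gene to
#' its closest variant site; a trans hotspot links a chosen site to a set
#' of target genes elsewhere in the genome.
#'
#' Defaults emulate droplet scRNA-seq of somatic cells: sparse per-gene
#' means (baseline log-mean around log 0.3 with SD 1), moderate
#' overdispersion (theta log-normal around 2), small batch effects (SD 0.1
#' on the log scale), and cell types distinguished by a fraction of marker
#' genes that are strongly upregulated in their type.
#'
#' @param truth a [SimTruth-class] from [simulatePedigree()].
#' @param nCis number of genes given a cis effect at their closest site.
#' @param cisEffect effect size (log scale per unit dosage) for cis
#'   effects; recycled, sign randomized.
#' @param hotspots optional data.frame with columns `site` (site index),
#'   `nTargets`, `effect`; each row plants one trans hotspot.
#' @param cellTypes character vector of cell-type names.
#' @param markerFrac fraction of genes serving as markers per cell type.
#' @param markerEffect log-scale upregulation of marker genes in their
#'   type.
#' @param typeEffectSd SD of the diffuse log-scale cell-type offsets given
#'   to every gene (default 0.2); marker genes receive `markerEffect` on
#'   top.
#' @param batchSd SD of log-scale batch offsets.
#' @param baselineMeanLog,baselineSdLog baseline log-mean distribution.
#' @param thetaMeanLog,thetaSdLog log-normal parameters for theta.
#' @param seed RNG seed.
#' @return The updated [SimTruth-class].
#' @export
plantEqtlArchitecture <- function(truth, nCis = 0, cisEffect = 1,
                                  hotspots = NULL,
                                  cellTypes = c("neuron", "muscle",
                                                "intestine", "hypodermis"),
                                  markerFrac = 0.1, markerEffect = 2,
                                  typeEffectSd = 0.2, batchSd = 0.1,
                                  baselineMeanLog = log(0.3),
                                  baselineSdLog = 1,
                                  thetaMeanLog = log(2), thetaSdLog = 0.4,
                                  seed = 1) {
  stopifnot(is(truth, "SimTruth"))
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)

  genes <- truth@genome@genes
  sites <- truth@genome@sites
  nG <- nrow(genes)
  nB <- truth@design@batches

  truth@baseline <- stats::rnorm(nG, baselineMeanLog, baselineSdLog)
  truth@theta <- stats::rlnorm(nG, thetaMeanLog, thetaSdLog)
  truth@batchEffects <- matrix(stats::rnorm(nG * nB, 0, batchSd), nG, nB,
                               dimnames = list(genes$gene, NULL))
  cte <- matrix(stats::rnorm(nG * length(cellTypes), 0, typeEffectSd), nG,
                length(cellTypes),
                dimnames = list(genes$gene, cellTypes))
  nMark <- max(1L, round(markerFrac * nG))
  markPool <- sample.int(nG, min(nG, nMark * length(cellTypes)))
  for (k in seq_along(cellTypes)) {
    mk <- markPool[seq_len(nMark) + (k - 1L) * nMark]
    mk <- mk[!is.na(mk)]
    cte[mk, k] <- cte[mk, k] + markerEffect
  }
  truth@cellTypeEffects <- cte
  truth@cellTypes <- cellTypes

  closest <- .closestSite(genes, sites)
  if (nCis > 0) {
    eligible <- which(!is.na(closest))
    pick <- sample(eligible, min(nCis, length(eligible)))
    truth@plantedCis <- data.frame(
      gene = genes$gene[pick],
      site = closest[pick],
      effect = rep_len(cisEffect, length(pick)) *
        sample(c(-1, 1), length(pick), replace = TRUE)
    )
  }
  if (!is.null(hotspots) && nrow(hotspots)) {
    out <- vector("list", nrow(hotspots))
    for (h in seq_len(nrow(hotspots))) {
      s <- hotspots$site[h]
      # targets on other chromosomes so they count as trans linkages
      far <- which(genes$chrom != sites$chrom[s])
      tg <- sample(far, min(hotspots$nTargets[h], length(far)))
      out[[h]] <- data.frame(gene = genes$gene[tg], site = s,
                             effect = rep(hotspots$effect[h], length(tg)) *
                               sample(c(-1, 1), length(tg), replace = TRUE),
                             hotspot = h)
    }
    truth@plantedTrans <- do.call(rbind, out)
  }
  validObject(truth)
  truth
}

# index of the closest variant site on the gene's own chromosome (NA if none)
.closestSite <- function(genes, sites) {
  vapply(seq_len(nrow(genes)), function(i) {
    onChrom <- which(sites$chrom == genes$chrom[i])
    if (!length(onChrom)) return(NA_integer_)
    onChrom[which.min(abs(sites$pos[onChrom] - genes$pos[i]))]
  }, integer(1))
}

#' Sample profiled cells from a simulated cross
#'
#' Draws cells uniformly (with replacement) from the dissociated
#' individuals, assigns each to a library batch and a cell type, and
#' optionally creates doublets (droplets containing two cells of distinct
#' individuals and cell types).
#'
#' @param truth a [SimTruth-class] with a planted architecture.
#' @param nCells number of droplets to profile; defaults to the design's
#'   `nCells`.
#' @param typeProbs cell-type proportions (named by `truth@cellTypes`);
#'   default slightly uneven.
#' @param doubletRate fraction of droplets containing two cells (default 0).
#' @param seed RNG seed.
#' @return data.frame with one row per droplet: `cell`, `individual`,
#'   `batch`, `cell_type`, `sex`, and for doublets `individual2`,
#'   `cell_type2` (NA otherwise).
#' @export
sampleCells <- function(truth, nCells = NULL, typeProbs = NULL,
                        doubletRate = 0, seed = 1) {
  stopifnot(is(truth, "SimTruth"), length(truth@cellTypes) >= 1)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  if (is.null(nCells)) nCells <- truth@design@nCells
  I <- nrow(truth@genotypes)
  types <- truth@cellTypes
  if (is.null(typeProbs)) {
    typeProbs <- rev(seq_along(types))
    typeProbs <- typeProbs / sum(typeProbs)
  }
  ind <- sample.int(I, nCells, replace = TRUE)
  ct <- sample(types, nCells, replace = TRUE, prob = typeProbs)
  dbl <- stats::runif(nCells) < doubletRate
  ind2 <- ifelse(dbl, sample.int(I, nCells, replace = TRUE), NA_integer_)
  ct2 <- rep(NA_character_, nCells)
  if (any(dbl)) {
    # force the second cell into a different type so the mixture is visible
    ct2[dbl] <- vapply(ct[dbl], function(t)
      sample(setdiff(types, t), 1L), "")
  }
  data.frame(
    cell = sprintf("cell%06d", seq_len(nCells)),
    individual = ind,
    batch = sample.int(truth@design@batches, nCells, replace = TRUE),
    cell_type = ct,
    sex = truth@sex[ind],
    individual2 = ind2,
    cell_type2 = ct2,
    stringsAsFactors = FALSE
  )
}

# mean parameter of an NB(size) count distribution whose median equals m
.nbMuForMedian <- function(m, size) {
  f <- function(mu) stats::pnbinom(m - 1L, size = size, mu = mu) - 0.5
  mu <- stats::uniroot(f, c(max(m / 10, 0.1), m * 10))$root
  # the median is the smallest k with CDF(k) >= 0.5; nudge off the boundary
  while (stats::qnbinom(0.5, size = size, mu = mu) < m) mu <- mu * 1.001
  mu
}

#' Simulate sparse genotype-informative allele counts
#'
#' Generates the per-cell UMI counts supporting each parental allele at the
#' genome's variant sites. Per cell, the total number of informative UMIs
#' is drawn from a negative-binomial distribution parameterized so that its
#' median equals `medianInformativeUmis`; UMIs are scattered uniformly over
#' sites, and each UMI reports the true allele with probability
#' `1 - errorRate` (heterozygotes: each allele with probability 1/2).
#' Doublet droplets draw each UMI from one of their two constituent
#' individuals with equal probability.
#'
#' @param truth a [SimTruth-class].
#' @param cells cell table from [sampleCells()].
#' @param medianInformativeUmis target median informative UMIs per cell
#'   (default 69).
#' @param errorRate per-read sequencing error rate (default 0.002).
#' @param sizeDispersion NB size parameter of the per-cell total
#'   distribution (default 2; heavier-tailed than Poisson, as observed for
#'   per-cell UMI yields).
#' @param seed RNG seed.
#' @return An [AlleleCounts-class] (sites x cells). Metadata records the
#'   seed and parameters.
#' @export
simulateAlleleCounts <- function(truth, cells, medianInformativeUmis = 69,
                                 errorRate = 0.002, sizeDispersion = 2,
                                 seed = 1) {
  stopifnot(is(truth, "SimTruth"), medianInformativeUmis >= 1)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  sites <- truth@genome@sites
  nS <- nrow(sites)
  nCells <- nrow(cells)
  mu <- .nbMuForMedian(medianInformativeUmis, sizeDispersion)
  totals <- stats::rnbinom(nCells, size = sizeDispersion, mu = mu)

  # one row per UMI, fully vectorized
  jAll <- rep.int(seq_len(nCells), totals)
  nU <- length(jAll)
  iAll <- sample.int(nS, nU, replace = TRUE)
  indOf <- cells$individual[jAll]
  ind2 <- cells$individual2[jAll]
  fromSecond <- !is.na(ind2) & stats::runif(nU) < 0.5
  indOf[fromSecond] <- ind2[fromSecond]
  g <- truth@genotypes[cbind(indOf, iAll)]
  # P(UMI reports CB allele) by genotype: 0 -> e, 1 -> 1/2, 2 -> 1 - e
  pCB <- c(errorRate, 0.5, 1 - errorRate)[g + 1L]
  alleleAll <- stats::runif(nU) < pCB
  mk <- function(keep) Matrix::sparseMatrix(
    i = iAll[keep], j = jAll[keep], x = rep.int(1, sum(keep)),
    dims = c(nS, nCells))
  n2 <- mk(!alleleAll)
  cb <- mk(alleleAll)
  ac <- AlleleCounts(n2, cb, sites, barcodes = cells$cell)
  metadata(ac) <- list(seed = seed,
                       medianInformativeUmis = medianInformativeUmis,
                       errorRate = errorRate,
                       sizeDispersion = sizeDispersion)
  ac
}

#' Simulate gamma-Poisson expression counts with planted effects
#'
#' Draws per-cell, per-gene UMI counts from a negative-binomial (gamma-
#' Poisson) model: the mean is
#' `exp(baseline + (logSize - centre) + batch + cellType + genetic)` with
#' per-gene overdispersion theta, where `logSize` is a per-cell log library
#' size target (log-normal) whose coefficient is one (pure compositional
#' scaling), and the genetic term sums the planted cis/trans effects times
#' the cell's additive dosage (true CB allele count / 2) at the planted
#' site. Doublet droplets sum the counts of their two constituent cells,
#' each simulated at half the library size.
#'
#' @param truth a [SimTruth-class] with a planted architecture.
#' @param cells cell table from [sampleCells()].
#' @param meanLogUmis mean of the per-cell log library-size target
#'   (default `log(2000)`).
#' @param sdLogUmis SD of the per-cell log library-size target.
#' @param seed RNG seed.
#' @return A [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with a sparse `counts` assay (genes x cells), `colData` columns
#'   `individual`, `batch`, `cell_type`, `total_umis`, `log_total` (log of
#'   realized total UMIs), and gene coordinates in `rowData`.
#' @export
simulateExpression <- function(truth, cells, meanLogUmis = log(2000),
                               sdLogUmis = 0.35, seed = 1) {
  stopifnot(is(truth, "SimTruth"), length(truth@baseline) > 0)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  genes <- truth@genome@genes
  nG <- nrow(genes)
  nCells <- nrow(cells)
  typeIdx <- match(cells$cell_type, truth@cellTypes)

  logSize <- stats::rnorm(nCells, meanLogUmis, sdLogUmis)

  # per-gene genetic offsets for a block of cells (columns)
  geneticOffset <- function(indiv) {
    off <- matrix(0, nG, length(indiv))
    arch <- rbind(truth@plantedCis[c("gene", "site", "effect")],
                  truth@plantedTrans[c("gene", "site", "effect")])
    if (nrow(arch)) {
      gi <- match(arch$gene, genes$gene)
      dose <- truth@genotypes[indiv, arch$site, drop = FALSE] / 2
      for (k in seq_len(nrow(arch)))
        off[gi[k], ] <- off[gi[k], ] + arch$effect[k] * dose[, k]
    }
    off
  }

  simBlock <- function(indiv, types, batch, lsize) {
    eta <- matrix(truth@baseline, nG, length(indiv)) +
      truth@cellTypeEffects[, types, drop = FALSE] +
      truth@batchEffects[, batch, drop = FALSE] +
      geneticOffset(indiv)
    eta <- sweep(eta, 2, lsize - meanLogUmis, "+")
    if (max(eta) > log(1e12)) stop("expression mean overflow (mu > 1e12)")
    mu <- exp(eta)
    cnt <- stats::rnbinom(length(mu), size = truth@theta, mu = mu)
    matrix(cnt, nG, length(indiv))
  }

  counts <- simBlock(cells$individual, typeIdx, cells$batch, logSize)
  isDbl <- !is.na(cells$individual2)
  if (any(isDbl)) {
    # each component at half size: log(size/2)
    half1 <- simBlock(cells$individual[isDbl], typeIdx[isDbl],
                      cells$batch[isDbl], logSize[isDbl] - log(2))
    half2 <- simBlock(cells$individual2[isDbl],
                      match(cells$cell_type2[isDbl], truth@cellTypes),
                      cells$batch[isDbl], logSize[isDbl] - log(2))
    counts[, isDbl] <- half1 + half2
  }

  total <- colSums(counts)
  if (any(total == 0)) {
    # guarantee a positive library for every droplet
    for (c in which(total == 0)) counts[sample.int(nG, 1L), c] <- 1L
    total <- colSums(counts)
  }
  dimnames(counts) <- list(genes$gene, cells$cell)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    rowData = DataFrame(genes),
    colData = DataFrame(cell = cells$cell,
                        individual = cells$individual,
                        batch = factor(cells$batch),
                        cell_type = cells$cell_type,
                        is_doublet = isDbl,
                        total_umis = total,
                        log_total = log(total))
  )
  metadata(sce) <- list(seed = seed, meanLogUmis = meanLogUmis,
                        sdLogUmis = sdLogUmis)
  sce
}
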