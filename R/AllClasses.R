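#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## Cross design
## ---------------------------------------------------------------------------

#' Design of a one-pot intercross single-cell experiment
#'
#' Describes the experimental design of a pooled segregant single-cell
#' RNA-seq experiment: how many recombinant individuals were seeded, what
#' fraction dissociated into the cell suspension, how many cells were
#' profiled, the intercross generation, and the number of library batches.
#' The effective number of genetically distinct individuals is
#' `round(nSeeded * dissociationRate)`.
#'
#' @slot nSeeded number of seeded segregant individuals.
#' @slot dissociationRate fraction of seeded individuals successfully
#'   dissociated, in (0, 1].
#' @slot nCells number of profiled cells.
#' @slot generations intercross generation (F_g); must be at least 2 so that
#'   a recombinant pool exists.
#' @slot batches number of library batches.
#' @export
setClass("CrossDesign",
  representation(
    nSeeded = "numeric",
    dissociationRate = "numeric",
    nCells = "numeric",
    generations = "numeric",
    batches = "numeric"
  )
)

setValidity("CrossDesign", function(object) {
  msg <- character()
  if (object@nSeeded < 1) msg <- c(msg, "nSeeded must be >= 1")
  if (object@dissociationRate <= 0 || object@dissociationRate > 1)
    msg <- c(msg, "dissociationRate must be in (0, 1]")
  if (object@nCells < 1) msg <- c(msg, "nCells must be >= 1")
  if (object@generations < 2)
    msg <- c(msg, "generations must be >= 2 (no recombinant pool otherwise)")
  if (object@batches < 1) msg <- c(msg, "batches must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CrossDesign
#'
#' @param nSeeded number of seeded segregants.
#' @param dissociationRate fraction of seeded individuals recovered as cells.
#' @param nCells number of profiled cells.
#' @param generations intercross generation (default 4).
#' @param batches number of library batches (default 1).
#' @return A [CrossDesign-class] object.
#' @examples
#' crossDesign(nSeeded = 192000, dissociationRate = 0.5, nCells = 55508)
#' @export
crossDesign <- function(nSeeded, dissociationRate, nCells,
                        generations = 4, batches = 1) {
  new("CrossDesign", nSeeded = nSeeded, dissociationRate = dissociationRate,
      nCells = nCells, generations = generations, batches = batches)
}

#' Effective number of dissociated individuals
#' @param design a [CrossDesign-class].
#' @return integer count, `round(nSeeded * dissociationRate)`.
#' @export
nIndividuals <- function(design) {
  stopifnot(is(design, "CrossDesign"))
  as.integer(round(design@nSeeded * design@dissociationRate))
}

setMethod("show", "CrossDesign", function(object) {
  cat("CrossDesign: F", object@generations, " intercross\n", sep = "")
  cat("  seeded: ", object@nSeeded,
      "  dissociation: ", object@dissociationRate,
      "  individuals: ", nIndividuals(object), "\n", sep = "")
  cat("  cells: ", object@nCells, "  batches: ", object@batches, "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## Simulated genome
## ---------------------------------------------------------------------------

#' A simulated genome layout
#'
#' Chromosome sizes, a monotone bp-to-cM genetic map, ordered biallelic
#' variant sites, and gene positions used by the cross simulator. The layout
#' emulates a compact nematode genome: a handful of autosomes plus one X
#' chromosome, with transcribed single-nucleotide variants segregating
#' between the two parental strains (labelled N2 and CB for the reference
#' and alternative backgrounds).
#'
#' @slot chromosomes data.frame with columns `chrom`, `length_bp`, `is_x`.
#' @slot map data.frame of genetic-map anchors: `chrom`, `bp`, `cM`,
#'   non-decreasing in cM within a chromosome.
#' @slot sites data.frame of variant sites: `chrom`, `pos`, `ref`, `alt`,
#'   ordered by (chrom, pos).
#' @slot genes data.frame of genes: `gene`, `chrom`, `pos`.
#' @export
setClass("SimGenome",
  representation(
    chromosomes = "data.frame",
    map = "data.frame",
    sites = "data.frame",
    genes = "data.frame"
  )
)

setValidity("SimGenome", function(object) {
  msg <- character()
  ch <- object@chromosomes
  if (!all(c("chrom", "length_bp", "is_x") %in% names(ch)))
    msg <- c(msg, "chromosomes needs columns chrom, length_bp, is_x")
  if (!all(c("chrom", "bp", "cM") %in% names(object@map)))
    msg <- c(msg, "map needs columns chrom, bp, cM")
  if (!all(c("chrom", "pos") %in% names(object@sites)))
    msg <- c(msg, "sites needs columns chrom, pos")
  if (length(msg)) return(msg)
  for (cc in ch$chrom) {
    m <- object@map[object@map$chrom == cc, ]
    if (nrow(m) < 2) msg <- c(msg, paste0("chromosome ", cc,
                                          " needs >= 2 map anchors"))
    else {
      if (is.unsorted(m$bp, strictly = TRUE))
        msg <- c(msg, paste0("map bp not strictly increasing on ", cc))
      if (is.unsorted(m$cM))
        msg <- c(msg, paste0("map cM decreasing in bp on ", cc))
    }
  }
  if (!all(object@sites$chrom %in% ch$chrom))
    msg <- c(msg, "every variant site must lie on a declared chromosome")
  ord <- order(match(object@sites$chrom, ch$chrom), object@sites$pos)
  if (!identical(ord, seq_len(nrow(object@sites))))
    msg <- c(msg, "sites must be ordered by (chrom, pos)")
  if (!all(is.finite(object@map$cM)))
    msg <- c(msg, "non-finite cM in map")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimGenome", function(object) {
  cat("SimGenome:", nrow(object@chromosomes), "chromosomes,",
      nrow(object@sites), "variant sites,",
      nrow(object@genes), "genes\n")
  cm <- vapply(split(object@map$cM, object@map$chrom), max, numeric(1))
  cat("  total map length:", sum(cm), "cM\n")
})

#' @describeIn SimGenome-class chromosome table accessor
#' @param genome a `SimGenome`.
#' @export
chromosomes <- function(genome) genome@chromosomes

#' @describeIn SimGenome-class variant site table accessor
#' @export
variantSites <- function(genome) genome@sites

#' @describeIn SimGenome-class gene table accessor
#' @export
genePositions <- function(genome) genome@genes

## ---------------------------------------------------------------------------
## Simulation ground truth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated cross
#'
#' Holds everything the simulator decided: individual genotypes at every
#' variant site (coded as the count of CB alleles, 0/1/2), individual sex,
#' the planted cis and trans eQTL architecture, per-gene baseline log
#' expression, per-gene overdispersion, batch and cell-type log-scale
#' effects. Downstream recovery tests compare inferred quantities against
#' this object.
#'
#' Genotypes on the X in hemizygous males carry a single allele and are
#' stored as 0 or 2 (the transmitted allele, counted twice) so that
#' homozygous-style allele counts are generated for them.
#'
#' @slot design the [CrossDesign-class] used.
#' @slot genome the [SimGenome-class] used.
#' @slot genotypes integer matrix, individuals x sites, values 0/1/2.
#' @slot sex character vector per individual: "hermaphrodite" or "male".
#' @slot plantedCis data.frame: `gene`, `site` (site index), `effect`.
#' @slot plantedTrans data.frame: `gene`, `site`, `effect`, `hotspot`.
#' @slot baseline per-gene intercept on the log scale.
#' @slot theta per-gene negative-binomial overdispersion (> 0).
#' @slot batchEffects genes x batches matrix of log-scale offsets.
#' @slot cellTypeEffects genes x cell-types matrix of log-scale offsets.
#' @slot cellTypes character vector of cell-type names.
#' @slot seed integer seed recorded for reproducibility.
#' @export
setClass("SimTruth",
  representation(
    design = "CrossDesign",
    genome = "SimGenome",
    genotypes = "matrix",
    sex = "character",
    plantedCis = "data.frame",
    plantedTrans = "data.frame",
    baseline = "numeric",
    theta = "numeric",
    batchEffects = "matrix",
    cellTypeEffects = "matrix",
    cellTypes = "character",
    seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  if (ncol(object@genotypes) != nrow(object@genome@sites))
    msg <- c(msg, "genotype columns must match genome variant sites")
  if (nrow(object@genotypes) != length(object@sex))
    msg <- c(msg, "one sex per individual required")
  if (length(object@genotypes) &&
      !all(object@genotypes %in% c(0L, 1L, 2L)))
    msg <- c(msg, "genotypes must be coded 0/1/2 (CB allele count)")
  ns <- nrow(object@genome@sites)
  for (df in list(object@plantedCis, object@plantedTrans)) {
    if (nrow(df)) {
      if (any(df$site < 1 | df$site > ns))
        msg <- c(msg, "planted effect at a marker not in the genome")
      if (!all(is.finite(df$effect)))
        msg <- c(msg, "planted effects must be finite")
    }
  }
  if (length(object@theta) && any(object@theta <= 0))
    msg <- c(msg, "theta must be > 0 per gene")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: ", nrow(object@genotypes), " F", object@design@generations,
      " individuals x ", ncol(object@genotypes), " sites\n", sep = "")
  cat("  planted cis effects:", nrow(object@plantedCis),
      " trans effects:", nrow(object@plantedTrans), "\n")
  cat("  genes:", length(object@baseline),
      " cell types:", length(object@cellTypes),
      " seed:", object@seed, "\n")
})

#' True genotype matrix of a simulation
#' @param truth a [SimTruth-class].
#' @return integer matrix individuals x sites with CB allele counts.
#' @export
trueGenotypes <- function(truth) truth@genotypes

#' Planted eQTL effect tables of a simulation
#' @param truth a [SimTruth-class].
#' @return list with elements `cis` and `trans` (data.frames).
#' @export
plantedEffects <- function(truth)
  list(cis = truth@plantedCis, trans = truth@plantedTrans)

## ---------------------------------------------------------------------------
## Genetic map with the intercross scale factor
## ---------------------------------------------------------------------------

#' Genetic map for HMM transition probabilities
#'
#' Piecewise-linear bp-to-cM anchors per chromosome, plus a scale factor
#' multiplying interpolated cM distances between adjacent sites. The default
#' scale factor of 0.4 compensates for a reference map built from ten
#' generations of intercrossing when the genotyped progeny derive from only
#' four: the expected number of crossovers accumulated, and hence the
#' effective map expansion, is smaller.
#'
#' @slot anchors data.frame with columns `chrom`, `bp`, `cM`.
#' @slot scaleFactor positive multiplier applied to interpolated cM
#'   distances (default 0.4).
#' @export
setClass("GeneticMap",
  representation(anchors = "data.frame", scaleFactor = "numeric")
)

setValidity("GeneticMap", function(object) {
  msg <- character()
  a <- object@anchors
  if (!all(c("chrom", "bp", "cM") %in% names(a)))
    msg <- c(msg, "anchors needs columns chrom, bp, cM")
  if (object@scaleFactor <= 0) msg <- c(msg, "scaleFactor must be > 0")
  if (length(msg)) return(msg)
  for (cc in unique(a$chrom)) {
    m <- a[a$chrom == cc, ]
    if (nrow(m) < 2)
      msg <- c(msg, paste0("chromosome ", cc, " needs >= 2 anchors"))
    else if (is.unsorted(m$cM[order(m$bp)]))
      msg <- c(msg, paste0("cM must be non-decreasing in bp on ", cc))
  }
  if (!all(is.finite(a$cM)) || !all(is.finite(a$bp)))
    msg <- c(msg, "non-finite map anchors")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneticMap
#' @param anchors data.frame of `chrom`, `bp`, `cM` anchors.
#' @param scaleFactor cM distance multiplier (default 0.4, the four- vs
#'   ten-generation intercross correction).
#' @return A [GeneticMap-class].
#' @export
geneticMap <- function(anchors, scaleFactor = 0.4) {
  anchors <- anchors[order(match(anchors$chrom, unique(anchors$chrom)),
                           anchors$bp), , drop = FALSE]
  rownames(anchors) <- NULL
  new("GeneticMap", anchors = anchors, scaleFactor = scaleFactor)
}

setMethod("show", "GeneticMap", function(object) {
  cm <- vapply(split(object@anchors$cM, object@anchors$chrom), max,
               numeric(1))
  cat("GeneticMap:", length(cm), "chromosomes,", sum(cm), "cM total,",
      "scale factor", object@scaleFactor, "\n")
})

## ---------------------------------------------------------------------------
## HMM parameters
## ---------------------------------------------------------------------------

#' Parameters of the genotyping hidden Markov model
#'
#' The per-read sequencing error rate and the prior genotype probabilities
#' over (NN, NC, CC). Autosomes use the F2-style prior (1/4, 1/2, 1/4). The
#' X chromosome uses (0.44, 0.44, 0.11), normalized to sum to one: the
#' cross is founded by N2 hermaphrodites mated to CB males, so N2
#' contributes twice as many X chromosomes and the CB homozygote is
#' correspondingly rarer.
#'
#' @slot errorRate per-read error rate e, in [0, 0.5).
#' @slot autosomalPrior probabilities over (NN, NC, CC) for autosomes.
#' @slot xPrior probabilities over (NN, NC, CC) for the X chromosome.
#' @export
setClass("HMMParams",
  representation(errorRate = "numeric", autosomalPrior = "numeric",
                 xPrior = "numeric")
)

setValidity("HMMParams", function(object) {
  msg <- character()
  if (object@errorRate < 0 || object@errorRate >= 0.5)
    msg <- c(msg, "errorRate must be in [0, 0.5)")
  for (nm in c("autosomalPrior", "xPrior")) {
    p <- slot(object, nm)
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, paste(nm, "must be 3 probabilities summing to 1"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct HMM parameters
#'
#' @param errorRate sequencing error rate per read (default 0.002).
#' @param autosomalPrior genotype prior (NN, NC, CC) on autosomes;
#'   default `c(0.25, 0.5, 0.25)`.
#' @param xPrior genotype prior on the X; default `c(0.44, 0.44, 0.11)`
#'   renormalized to sum to one.
#' @return An [HMMParams-class].
#' @export
hmmParams <- function(errorRate = 0.002,
                      autosomalPrior = c(0.25, 0.5, 0.25),
                      xPrior = c(0.44, 0.44, 0.11) / 0.99) {
  new("HMMParams", errorRate = errorRate,
      autosomalPrior = autosomalPrior / sum(autosomalPrior),
      xPrior = xPrior / sum(xPrior))
}

setMethod("show", "HMMParams", function(object) {
  cat("HMMParams: e =", object@errorRate, "\n")
  cat("  autosomal prior:", paste(signif(object@autosomalPrior, 4),
                                  collapse = ", "), "\n")
  cat("  X prior:", paste(signif(object@xPrior, 4), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Allele counts and genotype posteriors (SummarizedExperiment subclasses)
## ---------------------------------------------------------------------------

#' Per-cell allele-informative UMI counts
#'
#' A [SummarizedExperiment-class] with variant sites as rows and cells as
#' columns, carrying two sparse assays: `"N2"` (UMIs supporting the
#' reference parental allele) and `"CB"` (UMIs supporting the alternative
#' parental allele). Row data carries at least `chrom` and `pos`; sites are
#' ordered by (chrom, pos).
#'
#' @export
setClass("AlleleCounts", contains = "SummarizedExperiment")

setValidity("AlleleCounts", function(object) {
  msg <- character()
  if (!all(c("N2", "CB") %in% assayNames(object)))
    msg <- c(msg, 'assays "N2" and "CB" are required')
  rd <- rowData(object)
  if (!all(c("chrom", "pos") %in% names(rd)))
    msg <- c(msg, "rowData needs chrom and pos")
  if (length(msg)) return(msg)
  if (min(assay(object, "N2")) < 0 || min(assay(object, "CB")) < 0)
    msg <- c(msg, "counts must be non-negative")
  ord <- order(match(rd$chrom, unique(rd$chrom)), rd$pos)
  if (!identical(ord, seq_len(nrow(object))))
    msg <- c(msg, "sites must be ordered by (chrom, pos)")
  if (length(msg)) msg else TRUE
})

#' Construct an AlleleCounts object
#'
#' @param n2,cb sparse (or dense) matrices of UMI counts, sites x cells,
#'   supporting the N2 and CB alleles respectively.
#' @param sites data.frame/DataFrame with columns `chrom`, `pos` (and
#'   optionally `ref`, `alt`), one row per site, ordered by (chrom, pos).
#' @param barcodes optional cell identifiers (column names).
#' @return An [AlleleCounts-class].
#' @export
AlleleCounts <- function(n2, cb, sites, barcodes = NULL) {
  n2 <- methods::as(n2, "CsparseMatrix")
  cb <- methods::as(cb, "CsparseMatrix")
  if (!is.null(barcodes)) colnames(n2) <- colnames(cb) <- barcodes
  se <- SummarizedExperiment(assays = list(N2 = n2, CB = cb),
                             rowData = DataFrame(sites))
  new("AlleleCounts", se)
}

setMethod("show", "AlleleCounts", function(object) {
  tot <- Matrix::colSums(assay(object, "N2")) +
    Matrix::colSums(assay(object, "CB"))
  cat("AlleleCounts:", nrow(object), "sites x", ncol(object), "cells\n")
  cat("  median informative UMIs per cell:", stats::median(tot), "\n")
})

#' @describeIn AlleleCounts-class N2-supporting count assay
#' @param x an `AlleleCounts`.
#' @export
n2Counts <- function(x) assay(x, "N2")

#' @describeIn AlleleCounts-class CB-supporting count assay
#' @export
cbCounts <- function(x) assay(x, "CB")

#' @describeIn AlleleCounts-class site table (rowData) as data.frame
#' @export
siteInfo <- function(x) as.data.frame(rowData(x))

#' Per-cell, per-site genotype posteriors from the HMM
#'
#' A [SummarizedExperiment-class] with variant sites as rows and cells as
#' columns, with assays `pNN`, `pNC`, `pCC` (posterior probabilities of the
#' three genotypes; each column of the triple sums to one at every site)
#' and `dosage` (the additive coding `pCC + 0.5 * pNC`, in [0, 1]).
#'
#' @export
setClass("GenotypePosteriors", contains = "SummarizedExperiment")

setValidity("GenotypePosteriors", function(object) {
  msg <- character()
  need <- c("pNN", "pNC", "pCC", "dosage")
  if (!all(need %in% assayNames(object)))
    return(paste("assays", paste(need, collapse = ", "), "are required"))
  s <- assay(object, "pNN") + assay(object, "pNC") + assay(object, "pCC")
  if (length(s) && max(abs(s - 1)) > 1e-8)
    msg <- c(msg, "posterior probabilities must sum to 1 at every site")
  d <- assay(object, "dosage")
  if (length(d) && (min(d) < -1e-9 || max(d) > 1 + 1e-9))
    msg <- c(msg, "dosage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypePosteriors", function(object) {
  cat("GenotypePosteriors:", nrow(object), "sites x", ncol(object),
      "cells\n")
  cat("  mean dosage:", signif(mean(assay(object, "dosage")), 4), "\n")
})

#' Additive genotype dosage
#'
#' The additive coding of the genotype posterior used for eQTL mapping:
#' the posterior probability of the CB homozygote plus half the posterior
#' probability of the heterozygote, i.e. half the expected CB allele count.
#'
#' @param x a [GenotypePosteriors-class] object.
#' @return matrix sites x cells with values in [0, 1].
#' @export
dosage <- function(x) {
  stopifnot(is(x, "GenotypePosteriors"))
  assay(x, "dosage")
}

#' @describeIn GenotypePosteriors-class the three posterior probability
#'   assays as a list of matrices (sites x cells).
#' @param x a `GenotypePosteriors`.
#' @export
genotypeProbs <- function(x)
  list(pNN = assay(x, "pNN"), pNC = assay(x, "pNC"), pCC = assay(x, "pCC"))
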