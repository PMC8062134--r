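#' Emission probabilities at a genotype-informative site
#'
#' Probability of observing `r` reads supporting the N2 allele out of `D`
#' total reads at a site, for each of the three genotypes, under binomial
#' sampling of alleles with an independent per-read error rate `e`:
#' \deqn{P(Y\mid NN) = \binom{D}{r}(1-e)^r e^{D-r},\quad
#'       P(Y\mid NC) = \binom{D}{r}(1/2)^D,\quad
#'       P(Y\mid CC) = \binom{D}{r} e^r (1-e)^{D-r}.}
#' A site with `D = 0` is uninformative and returns (1, 1, 1).
#'
#' @param r reads supporting the N2 allele (vectorized).
#' @param D total reads at the site.
#' @param e per-read error rate.
#' @param log return log probabilities?
#' @return matrix with columns `NN`, `NC`, `CC`.
#' @examples
#' emissionProbs(1, 1, 0.002)  # (0.998, 0.5, 0.002)
#' @export
emissionProbs <- function(r, D, e = 0.002, log = FALSE) {
  if (any(r > D) || any(r < 0)) stop("need 0 <= r <= D")
  out <- cbind(NN = stats::dbinom(r, D, 1 - e, log = log),
               NC = stats::dbinom(r, D, 0.5, log = log),
               CC = stats::dbinom(r, D, e, log = log))
  out
}

#' Genotype transition matrix between adjacent sites
#'
#' Converts a (scaled) cM distance to a recombination fraction with
#' Haldane's map function, \eqn{\rho = (1 - e^{-2d/100})/2}, and treats the
#' two homolog transmissions as independent, giving the F2-style 3-state
#' transition matrix over (NN, NC, CC).
#'
#' @param dScaled genetic distance in cM (after map scaling); must be
#'   non-negative.
#' @return 3x3 row-stochastic matrix.
#' @examples
#' transitionMatrix(0)        # identity
#' transitionMatrix(1e9)      # rows approach (0.25, 0.5, 0.25)
#' @export
transitionMatrix <- function(dScaled) {
  if (dScaled < 0) stop("genetic distance must be non-negative")
  rho <- (1 - exp(-2 * dScaled / 100)) / 2
  .transitionFromRho(rho)
}

.transitionFromRho <- function(rho) {
  q <- 1 - rho
  matrix(c(q^2,       2 * rho * q,   rho^2,
           rho * q,   q^2 + rho^2,   rho * q,
           rho^2,     2 * rho * q,   q^2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("NN", "NC", "CC"), c("NN", "NC", "CC")))
}

#' Infer per-cell genotype posteriors with the forward-backward algorithm
#'
#' Runs an independent hidden Markov chain per chromosome (chains restart
#' at the chromosome's prior) over the ordered variant sites, with
#' emissions from [emissionProbs()], transitions from [transitionMatrix()]
#' on map-interpolated, scale-factor-adjusted cM gaps, and the autosomal or
#' X prior chosen by the chromosome's `is_x` flag (when `xChroms` names
#' it). Posteriors are exact smoothing probabilities; per-site
#' normalization keeps the recursion in a stable numeric range, and sites
#' with zero coverage contribute flat emissions.
#'
#' The computation is vectorized across cells: at each site the forward
#' and backward recursions update an (n cells x 3) matrix.
#'
#' @param counts an [AlleleCounts-class] (sites x cells).
#' @param map a [GeneticMap-class].
#' @param params an [HMMParams-class].
#' @param xChroms chromosome names treated as X-linked (default `"X"`).
#' @return A [GenotypePosteriors-class] with assays `pNN`, `pNC`, `pCC`,
#'   `dosage` (sites x cells).
#' @export
inferGenotypes <- function(counts, map, params = hmmParams(),
                           xChroms = "X") {
  stopifnot(is(counts, "AlleleCounts"), is(map, "GeneticMap"),
            is(params, "HMMParams"))
  sites <- siteInfo(counts)
  nS <- nrow(sites)
  nC <- ncol(counts)
  rmat <- as.matrix(n2Counts(counts))
  dmat <- rmat + as.matrix(cbCounts(counts))
  pNN <- pNC <- pCC <- matrix(NA_real_, nS, nC)

  for (cc in unique(sites$chrom)) {
    idx <- which(sites$chrom == cc)
    prior <- if (cc %in% xChroms) params@xPrior else params@autosomalPrior
    gaps <- if (length(idx) > 1)
      scaledGaps(map, sites$chrom[idx], sites$pos[idx]) else numeric(0)
    trans <- lapply(gaps, transitionMatrix)
    # emissions: list over sites of (cells x 3); computed in log space and
    # rescaled per cell so deep sites cannot underflow (posteriors are
    # invariant to per-site emission scaling)
    em <- lapply(idx, function(s) {
      le <- emissionProbs(rmat[s, ], dmat[s, ], params@errorRate,
                          log = TRUE)
      exp(le - apply(le, 1, max))
    })
    S <- length(idx)
    # forward pass, normalized per site
    alpha <- vector("list", S)
    a <- sweep(em[[1]], 2, prior, "*")
    a <- a / rowSums(a)
    alpha[[1]] <- a
    if (S > 1) for (s in 2:S) {
      a <- (a %*% trans[[s - 1]]) * em[[s]]
      a <- a / rowSums(a)
      alpha[[s]] <- a
    }
    # backward pass
    b <- matrix(1, nC, 3)
    post <- alpha[[S]] * b
    post <- post / rowSums(post)
    pNN[idx[S], ] <- post[, 1]; pNC[idx[S], ] <- post[, 2]
    pCC[idx[S], ] <- post[, 3]
    if (S > 1) for (s in (S - 1):1) {
      b <- (b * em[[s + 1]]) %*% t(trans[[s]])
      b <- b / rowSums(b)
      post <- alpha[[s]] * b
      post <- post / rowSums(post)
      pNN[idx[s], ] <- post[, 1]; pNC[idx[s], ] <- post[, 2]
      pCC[idx[s], ] <- post[, 3]
    }
  }

  dos <- pCC + 0.5 * pNC
  se <- SummarizedExperiment(
    assays = list(pNN = pNN, pNC = pNC, pCC = pCC, dosage = dos),
    rowData = rowData(counts), colData = colData(counts))
  metadata(se) <- list(errorRate = params@errorRate,
                       scaleFactor = map@scaleFactor,
                       xChroms = xChroms)
  new("GenotypePosteriors", se)
}

#' Expected number of cells with a unique genotype
#'
#' Closed-form "birthday problem" expectation: when `C` cells are sampled
#' (with replacement) from `I` equally likely individuals, the expected
#' number of cells whose individual was sampled exactly once is
#' \eqn{C (1 - 1/I)^{C-1}}.
#'
#' @param C number of cells sampled.
#' @param I number of individuals.
#' @return expected count of cells carrying a unique genotype.
#' @examples
#' expectedUniqueGenotypes(55508, 96000)
#' @export
expectedUniqueGenotypes <- function(C, I) {
  stopifnot(C >= 1, I >= 1)
  C * (1 - 1 / I)^(C - 1)
}

#' Count genotype collisions between cells
#'
#' Computes the Pearson correlation between the genome-wide dosage vectors
#' of all cell pairs and counts the cells whose maximal correlation with
#' any other cell exceeds a threshold; such cells likely share an
#' individual of origin. Cells with constant dosage vectors are excluded
#' (their correlation is undefined) with a message.
#'
#' @param dosageMatrix matrix of dosages, sites x cells (as produced by
#'   [dosage()]), or a [GenotypePosteriors-class].
#' @param threshold correlation threshold (default 0.9).
#' @return integer count of colliding cells.
#' @export
countGenotypeCollisions <- function(dosageMatrix, threshold = 0.9) {
  if (is(dosageMatrix, "GenotypePosteriors"))
    dosageMatrix <- dosage(dosageMatrix)
  if (ncol(dosageMatrix) < 2) stop("need at least 2 cells")
  v <- apply(dosageMatrix, 2, stats::var)
  if (any(v == 0)) {
    message("countGenotypeCollisions: excluding ", sum(v == 0),
            " cells with constant dosage")
    dosageMatrix <- dosageMatrix[, v > 0, drop = FALSE]
    if (ncol(dosageMatrix) < 2) return(0L)
  }
  cm <- stats::cor(dosageMatrix)
  diag(cm) <- -Inf
  sum(apply(cm, 1, max) > threshold)
}

#' Assign cells to a parental strain from summed allele counts
#'
#' A cell is called for a parent when at least `minSupport` informative UMI
#' counts support that parent's genotype and fewer than `minSupport`
#' support the other; otherwise it is unassigned.
#'
#' @param n2Support,cbSupport summed informative UMI counts per cell.
#' @param minSupport threshold (default 50).
#' @return character vector in `{"N2", "CB4856", "unassigned"}`.
#' @examples
#' assignParental(c(120, 60, 49), c(3, 55, 0))
#' @export
assignParental <- function(n2Support, cbSupport, minSupport = 50) {
  stopifnot(length(n2Support) == length(cbSupport))
  out <- rep("unassigned", length(n2Support))
  out[n2Support >= minSupport & cbSupport < minSupport] <- "N2"
  out[cbSupport >= minSupport & n2Support < minSupport] <- "CB4856"
  out
}
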