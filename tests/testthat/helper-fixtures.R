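# Shared fixtures and independent oracles for the test suite.

# Exact single-locus X-linked genotype distribution among hermaphrodites
# after g generations of the N2-hermaphrodite x CB-male cross, by direct
# recursion over egg and sperm allele frequencies (males are X0).
xFreqOracle <- function(generations) {
  herm <- c(NN = 0, NC = 1, CC = 0)  # F1 hermaphrodites
  male <- c(N = 1, C = 0)            # F1 males carry the maternal (N2) X
  if (generations < 1) stop("generations >= 1")
  g <- 1
  while (g < generations) {
    egg <- c(N = herm[["NN"]] + herm[["NC"]] / 2,
             C = herm[["CC"]] + herm[["NC"]] / 2)
    herm <- c(NN = egg[["N"]] * male[["N"]],
              NC = egg[["N"]] * male[["C"]] + egg[["C"]] * male[["N"]],
              CC = egg[["C"]] * male[["C"]])
    male <- egg
    g <- g + 1
  }
  herm
}

# Exhaustive-path posterior marginals for a single-cell HMM instance:
# sums over all 3^S state paths. Independent of the forward-backward code.
bruteForcePosterior <- function(r, d, gapsCm, prior, e) {
  S <- length(r)
  em <- cbind(dbinom(r, d, 1 - e), dbinom(r, d, 0.5), dbinom(r, d, e))
  Tm <- lapply(gapsCm, function(g) {
    rho <- (1 - exp(-2 * g / 100)) / 2
    q <- 1 - rho
    matrix(c(q^2, 2 * rho * q, rho^2,
             rho * q, q^2 + rho^2, rho * q,
             rho^2, 2 * rho * q, q^2), 3, 3, byrow = TRUE)
  })
  paths <- as.matrix(expand.grid(rep(list(1:3), S)))
  w <- apply(paths, 1, function(st) {
    p <- prior[st[1]] * em[1, st[1]]
    if (S > 1) for (s in 2:S)
      p <- p * Tm[[s - 1]][st[s - 1], st[s]] * em[s, st[s]]
    p
  })
  post <- vapply(seq_len(S), function(s)
    vapply(1:3, function(k) sum(w[paths[, s] == k]), numeric(1)),
    numeric(3))
  sweep(post, 2, colSums(post), "/")  # 3 x S
}

# A one-chromosome AlleleCounts for a single cell with given counts at
# equally spaced positions, plus a map in which cM positions are `cm`
# (scaleFactor 1 so scaled gaps equal raw gaps).
oneCellCounts <- function(r, d, cm) {
  pos <- seq(1e5, by = 1e5, length.out = length(r))
  anchors <- data.frame(chrom = "I", bp = pos, cM = cm)
  if (nrow(anchors) < 2)  # maps need two anchors even for one site
    anchors <- rbind(anchors,
                     data.frame(chrom = "I", bp = pos + 1e5, cM = cm + 1))
  gm <- geneticMap(anchors, scaleFactor = 1)
  ac <- AlleleCounts(matrix(r, ncol = 1), matrix(d - r, ncol = 1),
                     data.frame(chrom = "I", pos = pos))
  list(ac = ac, gm = gm)
}

# Small intercross study used by several files: one autosome, planted
# effects optional. Returns everything downstream stages need.
smallStudy <- function(nSites = 80, nGenes = 30, nCells = 400,
                       nIndividuals = 300, batches = 2, nCis = 0,
                       cisEffect = 1, hotspots = NULL, doubletRate = 0,
                       chromCm = 50, seed = 1, twoChrom = FALSE) {
  chroms <- if (twoChrom)
    data.frame(chrom = c("I", "II"), length_bp = c(10e6, 10e6),
               is_x = c(FALSE, FALSE))
  else data.frame(chrom = "I", length_bp = 15e6, is_x = FALSE)
  g <- simGenome(nSites = nSites, nGenes = nGenes, chromosomes = chroms,
                 chromCm = chromCm, seed = seed)
  d <- crossDesign(nSeeded = nIndividuals * 2, dissociationRate = 0.5,
                   nCells = nCells, batches = batches)
  tr <- simulatePedigree(d, g, seed = seed + 1)
  tr <- plantEqtlArchitecture(tr, nCis = nCis, cisEffect = cisEffect,
                              hotspots = hotspots, seed = seed + 2)
  cells <- sampleCells(tr, doubletRate = doubletRate, seed = seed + 3)
  ac <- simulateAlleleCounts(tr, cells, seed = seed + 4)
  sce <- simulateExpression(tr, cells, seed = seed + 5)
  gm <- geneticMap(g@map)
  list(genome = g, design = d, truth = tr, cells = cells, ac = ac,
       sce = sce, gm = gm)
}

# negative-binomial log-likelihood via stats::dnbinom, as an independent
# check of the explicit formula
dnbinomLogLik <- function(y, mu, theta)
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
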