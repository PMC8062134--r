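test_that("preprocessing normalizes, selects HVGs, scales and clips", {
  set.seed(20)
  nC <- 60
  counts <- matrix(rpois(6 * nC, 5), 6, nC,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:nC)))
  counts["g1", ] <- 0; counts["g1", 1:3] <- 1      # < 10 cells: dropped
  counts["g2", ] <- rpois(nC, 100)                 # mean above window
  cfg <- classifierConfig(targetSum = 100, hvgMeanRange = c(0.0125, 3),
                          hvgMinDispersion = 0, minCellsPerGene = 10)
  pp <- preprocessClassifier(counts, cfg)
  expect_false("g1" %in% pp$stats$genes)
  expect_false("g2" %in% pp$hvg)                   # mean outside window
  expect_true(all(c("g3", "g4") %in% pp$hvg))
  # per-cell normalization: doubling a cell's counts leaves features equal
  c2 <- counts[, 1, drop = FALSE] * 2
  colnames(c2) <- "dbl"
  f2 <- preprocessClassifier(cbind(counts, dbl = c2[, 1]), cfg)
  expect_equal(unname(f2$features["dbl", ]),
               unname(f2$features["c1", ]), tolerance = 1e-12)
  # z-scores are clipped at the configured ceiling
  spiky <- counts
  spiky["g3", 1] <- 5000
  fS <- preprocessClassifier(spiky, classifierConfig(
    targetSum = 100, hvgMinDispersion = 0, minCellsPerGene = 10,
    scaleClip = 2))
  expect_lte(max(fS$features), 2)
  # a zero-total cell is a named failure
  zc <- counts; zc[, 2] <- 0
  expect_error(preprocessClassifier(zc, cfg), "c2")
})

test_that("cell calling applies the doublet and low-quality rules in order", {
  probs <- rbind(
    c(0.50, 0.30, 0.20, 0.00),  # two classes > 0.2: doublet
    c(0.39, 0.31, 0.30, 0.00),  # doublet rule precedes low-quality
    c(0.95, 0.03, 0.02, 0.00),  # confident singlet
    c(0.41, 0.20, 0.39, 0.00),  # 0.41 and 0.39 both > 0.2: doublet
    c(0.41, 0.20, 0.20, 0.19),  # one class > 0.2, max >= 0.4: assigned
    c(0.39, 0.20, 0.21, 0.20))  # two > 0.2 again: doublet
  colnames(probs) <- c("a", "b", "c", "d")
  cfg <- classifierConfig()
  calls <- callCells(probs, cfg)
  expect_equal(calls$label,
               c("doublet", "doublet", "a", "doublet", "a", "doublet"))
  # a lone sub-0.4 maximum is low quality
  lone <- matrix(c(0.39, 0.20, 0.20, 0.20, 0.01), 1)
  colnames(lone) <- c("a", "b", "c", "d", "e")
  expect_equal(callCells(lone, cfg)$label, "low_quality")
  expect_error(callCells(matrix(c(0.5, 0.2), 1), cfg), "sum to 1")
})

test_that("the classifier separates a linearly separable toy problem", {
  set.seed(21)
  n <- 60
  x <- rbind(matrix(rnorm(n * 5, 0), n),
             matrix(rnorm(n * 5, 4), n))
  lab <- rep(c("a", "b"), each = n)
  cfg <- classifierConfig(C = 1)
  model <- fitCellTypeClassifier(x, lab, cfg)
  pr <- predictCellTypeProbs(model, x)
  acc <- mean(colnames(pr)[max.col(pr)] == lab)
  expect_gte(acc, 0.99)
  # classes smaller than the fold count are rejected by name
  expect_error(fitCellTypeClassifier(x[c(1:3, 61:70), ],
                                     lab[c(1:3, 61:70)], cfg), "a")
})

test_that("coefficients shrink monotonically as C decreases", {
  set.seed(22)
  n <- 80
  x <- rbind(matrix(rnorm(n * 4, 0), n), matrix(rnorm(n * 4, 1.5), n))
  lab <- rep(c("a", "b"), each = n)
  norms <- vapply(c(1, 1e-1, 1e-2, 1e-3, 1e-4), function(C) {
    m <- fitCellTypeClassifier(x, lab, classifierConfig(C = C))
    sum(vapply(m$fit$beta, function(b) sum(b^2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("label permutation drives held-out accuracy to chance", {
  set.seed(23)
  n <- 200
  x <- matrix(rnorm(n * 10), n)
  lab <- sample(rep(c("a", "b", "c", "d"), each = n / 4))
  pr <- crossValProbabilities(x, lab, classifierConfig(C = 1), seed = 2)
  acc <- mean(colnames(pr)[max.col(pr)] == lab)
  expect_lt(abs(acc - 0.25), 0.1)
})

test_that("labels transfer across batches of the same generative process", {
  st <- smallStudy(nSites = 20, nGenes = 300, nCells = 2000,
                   nIndividuals = 300, batches = 2, seed = 131)
  cd <- SummarizedExperiment::colData(st$sce)
  cfg <- classifierConfig()
  b1 <- cd$batch == 1
  pp <- preprocessClassifier(
    SummarizedExperiment::assay(st$sce, "counts")[, b1], cfg)
  model <- fitCellTypeClassifier(pp$features, cd$cell_type[b1], cfg)
  ppNew <- preprocessClassifier(
    SummarizedExperiment::assay(st$sce, "counts")[, !b1], cfg,
    stats = pp$stats)
  pr <- predictCellTypeProbs(model, ppNew$features)
  transferred <- colnames(pr)[max.col(pr)]
  expect_gte(mean(transferred == cd$cell_type[!b1]), 0.95)
})
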