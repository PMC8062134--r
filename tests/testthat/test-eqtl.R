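test_that("the expression filter counts cells with non-zero counts", {
  m <- matrix(0, 3, 30, dimnames = list(c("a", "b", "c"), NULL))
  m[1, 1:20] <- 1   # exactly 20 cells
  m[2, 1:19] <- 5   # 19 cells
  expect_identical(filterExpressed(m), "a")
  expect_identical(filterExpressed(m, minCells = 1), c("a", "b"))
  expect_message(expect_length(filterExpressed(m * 0), 0), "no gene")
})

test_that("marker pruning drops duplicates and standardizes dosages", {
  set.seed(10)
  nC <- 50
  d1 <- runif(nC); d2 <- runif(nC); d3 <- runif(nC)
  dos <- rbind(d1, d1, d2, d3)  # sites x cells; site 2 duplicates site 1
  sites <- data.frame(chrom = "I", pos = c(1e5, 2e5, 3e5, 4e5))
  mk <- pruneMarkers(dos, sites)
  expect_equal(mk$info$site, c(1, 3, 4))
  expect_lt(max(abs(colMeans(mk$dosage))), 1e-8)
  # population variance = 1
  expect_lt(max(abs(colMeans(mk$dosage^2) - 1)), 1e-6)
  # constant markers are dropped with a message
  expect_message(
    mk2 <- pruneMarkers(rbind(d1, rep(0.5, nC)), sites[1:2, ]),
    "constant")
  expect_equal(mk2$info$site, 1)
  # independent markers are all kept
  expect_equal(nrow(pruneMarkers(dos[c(1, 3, 4), ], sites[1:3, ])$info), 3)
})

test_that("pruning enforces the LD ceiling between adjacent kept markers", {
  st <- smallStudy(nSites = 120, nCells = 150, seed = 81)
  post <- inferGenotypes(st$ac, st$gm)
  mk <- pruneMarkers(post, map = st$gm)
  D <- mk$dosage
  if (ncol(D) > 1) {
    adj <- vapply(seq_len(ncol(D) - 1), function(j)
      abs(cor(D[, j], D[, j + 1])), numeric(1))
    expect_true(all(adj <= 0.9999 + 1e-12))
  }
  # retained spacing is coarser than the raw site spacing
  expect_lte(ncol(D), nrow(siteInfo(st$ac)))
})

test_that("cis and trans scans agree at the closest marker and find planted effects", {
  st <- smallStudy(nSites = 60, nGenes = 25, nCells = 700, nCis = 6,
                   cisEffect = 1, seed = 91)
  post <- inferGenotypes(st$ac, st$gm)
  mk <- pruneMarkers(post, map = st$gm)
  cis <- cisScan(st$sce, mk)
  tr <- transScan(st$sce, mk, thetas = setNames(cis$theta, cis$gene))
  # invariant: the trans LOD at the gene's closest marker equals the cis LOD
  for (k in seq_len(nrow(cis))) {
    g <- cis$gene[k]
    expect_equal(unname(tr$lod[g, cis$marker[k]]), cis$lod[k],
                 tolerance = 1e-4)
  }
  # planted effects: detected strongly and with the planted sign
  eff <- plantedEffects(st$truth)$cis
  hits <- cis[match(eff$gene, cis$gene), ]
  expect_gte(sum(hits$p < 0.01, na.rm = TRUE), nrow(eff) - 1)
  ok <- !is.na(hits$effect)
  expect_true(all(sign(hits$effect[ok]) == sign(eff$effect[ok])))
  # trans peak for a cis gene sits on the gene's chromosome at high LOD
  top <- tr$peaks[tr$peaks$gene == eff$gene[which.max(abs(eff$effect))], ]
  expect_equal(top$chrom[which.max(top$lod)], "I")
  # the 1.5-LOD interval contains the peak marker
  expect_true(all(tr$peaks$ci_lo_marker <= tr$peaks$marker &
                    tr$peaks$marker <= tr$peaks$ci_hi_marker))
})

test_that("doubling library sizes leaves the genetic effect unchanged", {
  st <- smallStudy(nSites = 40, nGenes = 12, nCells = 300, nCis = 2,
                   batches = 1, seed = 101)
  post <- inferGenotypes(st$ac, st$gm)
  mk <- pruneMarkers(post, map = st$gm)
  cis1 <- cisScan(st$sce, mk)
  sce2 <- st$sce
  SummarizedExperiment::colData(sce2)$log_total <-
    SummarizedExperiment::colData(sce2)$log_total + log(2)
  cis2 <- cisScan(sce2, mk)
  expect_equal(cis2$effect, cis1$effect, tolerance = 1e-3)
  expect_equal(cis2$lod, cis1$lod, tolerance = 1e-3)
})

test_that("LOD-drop intervals behave on flat and spiked curves", {
  expect_equal(lodDropCi(rep(2, 7)), c(1, 7))        # flat: whole chrom
  spike <- c(0, 0, 9, 0, 0)
  expect_equal(lodDropCi(spike), c(3, 3))            # isolated spike
  curve <- c(1, 4, 5, 4, 1)
  expect_equal(lodDropCi(curve), c(2, 4))
  expect_equal(lodDropCi(c(3, 3, 1), drop = 0.5), c(1, 2))  # leftmost tie
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.037), 0.037)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.5, 1.2)))
})

test_that("correlation-to-LOD matches the Gaussian likelihood-ratio form", {
  expect_equal(lodFromCorrelation(0, 50), 0)
  expect_equal(lodFromCorrelation(0.5, 100), 15.0515, tolerance = 1e-4)
  # equivalence with the nested linear-model likelihood ratio
  set.seed(11)
  x <- rnorm(120); y <- x + rnorm(120)
  r2 <- cor(x, y)^2
  n <- length(x)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(resid(lm(y ~ x))^2)
  lodLm <- n / 2 * log10(rss0 / rss1)
  expect_equal(lodFromCorrelation(r2, n), lodLm, tolerance = 1e-9)
  expect_gt(lodFromCorrelation(0.6, 100), lodFromCorrelation(0.5, 100))
  expect_gt(lodFromCorrelation(0.5, 200), lodFromCorrelation(0.5, 100))
  expect_error(lodFromCorrelation(1, 100), "R\\^2")
})

test_that("Stouffer combination and direction concordance follow their forms", {
  expect_equal(stoufferCombine(1.7), 1.7)
  expect_equal(stoufferCombine(c(1.96, 1.96)), 2 * 1.96 / sqrt(2),
               tolerance = 1e-9)
  expect_equal(stoufferCombine(c(2, -2)), 0)
  expect_equal(stoufferCombine(c(1, 2), weights = c(2, 1)),
               4 / sqrt(5), tolerance = 1e-12)

  # the two concordance regimes: chance-level and strongly concordant
  chance <- directionConcordance(rep(c(1, -1), c(33, 36)), rep(1, 69))
  expect_equal(chance$nSame, 33)
  expect_equal(chance$nOpposite, 36)
  expect_gt(chance$p, 0.5)
  strong <- directionConcordance(rep(c(1, -1), c(88, 6)), rep(1, 94))
  expect_lt(strong$p, 1e-6)
  even <- directionConcordance(rep(c(1, -1), each = 10), rep(1, 20))
  expect_gt(even$p, 0.99)
  expect_message(directionConcordance(c(1, 0, -1), c(1, 1, 1)),
                 "excluding")
})

test_that("the FDR curve is monotone, clipped and degenerate-safe", {
  obs <- c(0.5, 1.2, 2.4, 3.1, 4.8)
  # identical observed and permuted distributions: FDR 1 everywhere
  perm <- cbind(obs, obs, obs)
  fc <- fdrFromPermutations(obs, perm)
  expect_true(all(fc$fdr[!is.na(fc$fdr)] == 1))
  expect_equal(unname(fc$adjust(obs)), rep(1, 5))
  # null permutations far below observed: FDR reaches 0 at the top
  fc2 <- fdrFromPermutations(obs, matrix(0.01, 5, 3))
  expect_true(all(diff(fc2$fdr[!is.na(fc2$fdr)]) <= 0))
  expect_lt(fc2$adjust(4.8), 0.21)
  expect_true(all(fc2$fdr >= 0 & fc2$fdr <= 1, na.rm = TRUE))
})

test_that("within-batch permutation keeps cells in their batch", {
  batch <- rep(c("a", "b"), c(10, 15))
  idx <- permuteWithinBatch(batch, seed = 3)
  expect_identical(batch[idx], batch)
  expect_identical(sort(idx), 1:25)
  expect_false(identical(idx, 1:25))
  # segregant mode: cells of one individual stay together as a block
  groups <- c(rep(1:5, each = 2), rep(6:10, each = 3))
  idxG <- permuteWithinBatch(batch, seed = 4, groups = groups)
  expect_identical(batch[idxG], batch)
  expect_identical(sort(idxG), 1:25)
  gperm <- groups[idxG]
  expect_true(all(rle(gperm[1:10])$lengths >= 2))
})

test_that("permutation FDR separates planted cis effects from nulls", {
  st <- smallStudy(nSites = 50, nGenes = 24, nCells = 600, nCis = 6,
                   cisEffect = 1.2, seed = 111)
  post <- inferGenotypes(st$ac, st$gm)
  mk <- pruneMarkers(post, map = st$gm)
  cis <- cisScan(st$sce, mk)
  pf <- cisPermutationFdr(st$sce, mk, cis, nPerm = 4, seed = 5)
  res <- pf$result
  eff <- plantedEffects(st$truth)$cis
  planted <- res$gene %in% eff$gene
  called <- res$gene[res$fdr <= 0.1]
  expect_gte(sum(called %in% eff$gene), 4)
  # false-discovery proportion among calls stays moderate
  if (length(called) > 0)
    expect_lte(mean(!(called %in% eff$gene)), 0.34)
})
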