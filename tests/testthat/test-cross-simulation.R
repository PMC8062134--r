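test_that("F2 autosomal genotype frequencies are Mendelian", {
  g <- simGenome(nSites = 12, nGenes = 5,
                 chromosomes = data.frame(chrom = "I", length_bp = 10e6,
                                          is_x = FALSE),
                 chromCm = 50, seed = 1)
  d <- crossDesign(nSeeded = 20000, dissociationRate = 0.5,
                   nCells = 10, generations = 2)
  tr <- simulatePedigree(d, g, seed = 2)
  G <- trueGenotypes(tr)
  for (s in c(1, 6, 12)) {
    freq <- tabulate(G[, s] + 1L, 3L) / nrow(G)
    expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.03)
  }
})

test_that("F4 X-linked hermaphrodite frequencies match the exact pedigree recursion", {
  expected <- xFreqOracle(4)
  expect_equal(unname(expected), c(15, 14, 3) / 32)  # frozen closed form
  g <- simGenome(nSites = 8, nGenes = 5,
                 chromosomes = data.frame(chrom = "X", length_bp = 10e6,
                                          is_x = TRUE),
                 chromCm = 50, seed = 1)
  d <- crossDesign(nSeeded = 16000, dissociationRate = 0.5, nCells = 10)
  tr <- simulatePedigree(d, g, seed = 3)
  herm <- tr@sex == "hermaphrodite"
  freq <- tabulate(trueGenotypes(tr)[herm, 4] + 1L, 3L) / sum(herm)
  expect_lt(max(abs(freq - expected)), 0.04)
  # males are hemizygous: stored as homozygous-style codes only
  expect_true(all(trueGenotypes(tr)[!herm, ] %in% c(0L, 2L)))
})

test_that("an F1 design is rejected (no recombinant pool)", {
  expect_error(crossDesign(nSeeded = 100, dissociationRate = 0.5,
                           nCells = 10, generations = 1),
               "generations")
})

test_that("mean crossovers per meiosis equals the map length in Morgans", {
  set.seed(7)
  h1 <- sceQTL:::.newHomolog(0L)
  h2 <- sceQTL:::.newHomolog(1L)
  L <- 120  # 1.2 Morgans
  nxo <- replicate(4000, sceQTL:::.gamete(h1, h2, L)$nxo)
  se <- sd(nxo) / sqrt(length(nxo))
  expect_lt(abs(mean(nxo) - L / 100), 3 * se + 1e-9)
  # crossovers are visible as segment breaks in a fully heterozygous parent
  gam <- sceQTL:::.gamete(h1, h2, L)
  expect_lte(length(gam$breaks), gam$nxo)
})

test_that("autosomal CB allele frequency stays at one half across generations", {
  g <- simGenome(nSites = 10, nGenes = 5,
                 chromosomes = data.frame(chrom = "I", length_bp = 10e6,
                                          is_x = FALSE),
                 chromCm = 50, seed = 1)
  for (gen in c(2, 4)) {
    d <- crossDesign(nSeeded = 8000, dissociationRate = 0.5, nCells = 10,
                     generations = gen)
    tr <- simulatePedigree(d, g, seed = gen)
    p <- mean(trueGenotypes(tr)) / 2
    expect_lt(abs(p - 0.5), 0.03)
  }
})

test_that("allele counts honor genotypes, error rate and the median target", {
  st <- smallStudy(nSites = 40, nCells = 600, seed = 11)
  # error_rate = 0: every count at a homozygous site supports the truth
  ac0 <- simulateAlleleCounts(st$truth, st$cells, errorRate = 0,
                              seed = 12)
  n2 <- as.matrix(n2Counts(ac0)); cb <- as.matrix(cbCounts(ac0))
  G <- trueGenotypes(st$truth)[st$cells$individual, ]  # cells x sites
  expect_true(all(cb[t(G) == 0L] == 0))
  expect_true(all(n2[t(G) == 2L] == 0))
  # median informative UMIs within +/-3 of the target at 10,000 cells
  big <- sampleCells(st$truth, nCells = 10000, seed = 13)
  acBig <- simulateAlleleCounts(st$truth, big, seed = 14)
  tot <- Matrix::colSums(n2Counts(acBig)) + Matrix::colSums(cbCounts(acBig))
  expect_lte(abs(median(tot) - 69), 3)
  # two cells from one individual: same genotype row, independent counts
  ij <- which(st$cells$individual == st$cells$individual[1])
  if (length(ij) >= 2) {
    expect_identical(G[ij[1], ], G[ij[2], ])
  }
})

test_that("expression counts are marginally gamma-Poisson with the stated theta", {
  g <- simGenome(nSites = 10, nGenes = 250,
                 chromosomes = data.frame(chrom = "I", length_bp = 10e6,
                                          is_x = FALSE),
                 chromCm = 50, seed = 21)
  d <- crossDesign(nSeeded = 100, dissociationRate = 0.5, nCells = 200)
  tr <- simulatePedigree(d, g, seed = 22)
  # homogeneous parameters: no batch / type / size variation
  tr <- plantEqtlArchitecture(tr, nCis = 0, cellTypes = "only",
                              markerFrac = 0.01, markerEffect = 0,
                              typeEffectSd = 0,
                              batchSd = 0, baselineMeanLog = log(2),
                              baselineSdLog = 0, thetaMeanLog = log(2),
                              thetaSdLog = 0, seed = 23)
  cells <- sampleCells(tr, seed = 24)
  sce <- simulateExpression(tr, cells, sdLogUmis = 0, seed = 25)
  y <- as.vector(as.matrix(SummarizedExperiment::assay(sce, "counts")))
  mu <- mean(y)
  expect_lt(abs(mu - 2) / 2, 0.1)
  expect_lt(abs(var(y) - (mu + mu^2 / 2)) / (mu + mu^2 / 2), 0.12)
})

test_that("a planted cis effect shifts means by exp(effect x dosage difference)", {
  g <- simGenome(nSites = 10, nGenes = 60,
                 chromosomes = data.frame(chrom = "I", length_bp = 10e6,
                                          is_x = FALSE),
                 chromCm = 50, seed = 31)
  d <- crossDesign(nSeeded = 1200, dissociationRate = 0.5, nCells = 4000)
  tr <- simulatePedigree(d, g, seed = 32)
  tr <- plantEqtlArchitecture(tr, nCis = 1, cisEffect = 1,
                              cellTypes = "only", markerEffect = 0,
                              typeEffectSd = 0,
                              batchSd = 0, baselineMeanLog = log(2),
                              baselineSdLog = 0, thetaSdLog = 0,
                              seed = 33)
  cells <- sampleCells(tr, seed = 34)
  sce <- simulateExpression(tr, cells, sdLogUmis = 0, seed = 35)
  eff <- plantedEffects(tr)$cis
  y <- as.matrix(SummarizedExperiment::assay(sce, "counts"))[eff$gene, ]
  geno <- trueGenotypes(tr)[cells$individual, eff$site]
  ratio <- mean(y[geno == 2L]) / mean(y[geno == 0L])
  expect_lt(abs(log(ratio) - eff$effect), 0.25)  # delta dosage = 1
})

test_that("the Poisson limit holds as theta grows", {
  g <- simGenome(nSites = 10, nGenes = 150,
                 chromosomes = data.frame(chrom = "I", length_bp = 10e6,
                                          is_x = FALSE),
                 chromCm = 50, seed = 41)
  d <- crossDesign(nSeeded = 100, dissociationRate = 0.5, nCells = 200)
  tr <- simulatePedigree(d, g, seed = 42)
  tr <- plantEqtlArchitecture(tr, nCis = 0, cellTypes = "only",
                              markerEffect = 0, typeEffectSd = 0,
                              batchSd = 0,
                              baselineMeanLog = log(2), baselineSdLog = 0,
                              thetaMeanLog = log(1e8), thetaSdLog = 0,
                              seed = 43)
  cells <- sampleCells(tr, seed = 44)
  sce <- simulateExpression(tr, cells, sdLogUmis = 0, seed = 45)
  y <- as.vector(as.matrix(SummarizedExperiment::assay(sce, "counts")))
  expect_lt(abs(var(y) / mean(y) - 1), 0.05)
})

test_that("doublet droplets mix two individuals and two cell types", {
  st <- smallStudy(nCells = 500, doubletRate = 0.2, seed = 51)
  dbl <- !is.na(st$cells$individual2)
  expect_gt(sum(dbl), 50)
  expect_true(all(st$cells$cell_type[dbl] != st$cells$cell_type2[dbl]))
  cd <- SummarizedExperiment::colData(st$sce)
  expect_identical(unname(cd$is_doublet), unname(dbl))
})
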