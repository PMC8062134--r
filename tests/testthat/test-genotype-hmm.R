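test_that("map interpolation is linear, anchored and scaled", {
  gm <- geneticMap(data.frame(chrom = "I", bp = c(0, 2e6, 4e6),
                              cM = c(0, 2, 10)))
  expect_equal(interpolateMap(gm, "I", 2e6), 2)          # at an anchor
  expect_equal(interpolateMap(gm, "I", 1e6), 1)          # midway 0..2 cM
  expect_equal(interpolateMap(gm, "I", 3e6), 6)
  # scale factor 0.4: a raw 5 cM adjacent gap becomes 2 cM
  gm2 <- geneticMap(data.frame(chrom = "I", bp = c(0, 1e6),
                               cM = c(0, 5)), scaleFactor = 0.4)
  expect_equal(scaledGaps(gm2, c("I", "I"), c(0, 1e6)), 2)
  # beyond the last anchor: terminal-segment extrapolation, with a message
  expect_message(cm <- interpolateMap(gm, "I", 5e6), "extrapolat")
  expect_equal(cm, 14)
})

test_that("emission probabilities follow the binomial error model", {
  expect_equal(unname(emissionProbs(0, 0, 0.002)[1, ]), c(1, 1, 1))
  e1 <- emissionProbs(1, 1, 0.002)[1, ]
  expect_equal(unname(e1), c(0.998, 0.5, 0.002))
  e2 <- emissionProbs(2, 3, 0.002)[1, ]
  # direct binomial pmf evaluation
  expect_equal(unname(e2),
               c(dbinom(2, 3, 0.998), dbinom(2, 3, 0.5),
                 dbinom(2, 3, 0.002)))
  expect_equal(unname(e2), c(5.976024e-3, 0.375, 1.197604e-5),
               tolerance = 1e-6)
  expect_error(emissionProbs(4, 3, 0.002), "r <= D")
})

test_that("transition matrices are Haldane-derived and row-stochastic", {
  expect_equal(transitionMatrix(0), diag(3), ignore_attr = TRUE)
  for (d in c(0.1, 1, 5, 20, 100)) {
    Tm <- transitionMatrix(d)
    expect_equal(unname(rowSums(Tm)), c(1, 1, 1))
    expect_true(all(Tm >= 0))
  }
  far <- transitionMatrix(1e6)
  for (i in 1:3)
    expect_equal(unname(far[i, ]), c(0.25, 0.5, 0.25), tolerance = 1e-9)
  expect_error(transitionMatrix(-1), "non-negative")
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:6) {
    S <- sample(2:8, 1)
    d <- rpois(S, 1.2)
    r <- rbinom(S, d, 0.5)
    gaps <- runif(S - 1, 0, 25)
    oc <- oneCellCounts(r, d, c(0, cumsum(gaps)))
    post <- inferGenotypes(oc$ac, oc$gm)
    pk <- genotypeProbs(post)
    fb <- rbind(pk$pNN[, 1], pk$pNC[, 1], pk$pCC[, 1])
    bf <- bruteForcePosterior(r, d, gaps, c(0.25, 0.5, 0.25), 0.002)
    expect_lt(max(abs(fb - bf)), 1e-10)
  }
})

test_that("single-site posteriors follow Bayes rule under each prior", {
  oc <- oneCellCounts(1, 1, 0)
  post <- genotypeProbs(inferGenotypes(oc$ac, oc$gm))
  # prior x emission, normalized: (0.25*0.998, 0.5*0.5, 0.25*0.002)/0.5
  expect_equal(c(post$pNN[1, 1], post$pNC[1, 1], post$pCC[1, 1]),
               c(0.499, 0.5, 0.001), tolerance = 1e-9)
  # X prior applies when the chromosome is flagged
  pos <- 1e5
  gmX <- geneticMap(data.frame(chrom = "X", bp = c(1, 2e5), cM = c(0, 1)),
                    scaleFactor = 1)
  acX <- AlleleCounts(matrix(0, 1, 1), matrix(0, 1, 1),
                      data.frame(chrom = "X", pos = pos))
  pX <- genotypeProbs(inferGenotypes(acX, gmX))
  xp <- c(0.44, 0.44, 0.11) / 0.99
  expect_equal(c(pX$pNN[1, 1], pX$pNC[1, 1], pX$pCC[1, 1]), xp,
               tolerance = 1e-9)
})

test_that("a cell with no informative counts recovers the prior everywhere", {
  oc <- oneCellCounts(rep(0, 5), rep(0, 5), c(0, 3, 9, 20, 40))
  post <- genotypeProbs(inferGenotypes(oc$ac, oc$gm))
  expect_equal(unname(post$pNN[, 1]), rep(0.25, 5), tolerance = 1e-12)
  expect_equal(unname(post$pNC[, 1]), rep(0.5, 5), tolerance = 1e-12)
})

test_that("posterior rows are normalized and dosage is the additive coding", {
  st <- smallStudy(nSites = 40, nCells = 120, seed = 61)
  post <- inferGenotypes(st$ac, st$gm)
  pk <- genotypeProbs(post)
  expect_lt(max(abs(pk$pNN + pk$pNC + pk$pCC - 1)), 1e-9)
  expect_equal(dosage(post), pk$pCC + 0.5 * pk$pNC, tolerance = 1e-12)
  expect_true(all(dosage(post) >= 0 & dosage(post) <= 1))
})

test_that("adding N2 support never decreases the N2 posterior at a site", {
  base <- c(0, 2, 0, 1, 0)
  depth <- c(1, 3, 0, 2, 2)
  cm <- c(0, 4, 10, 18, 30)
  prev <- -Inf
  for (extra in 0:6) {
    r <- base; d <- depth
    r[3] <- extra; d[3] <- extra  # N2-supporting reads only
    oc <- oneCellCounts(r, d, cm)
    p <- genotypeProbs(inferGenotypes(oc$ac, oc$gm))$pNN[3, 1]
    expect_gte(p, prev - 1e-12)
    prev <- p
  }
})

test_that("deep error-free coverage pins the homozygous state", {
  oc <- oneCellCounts(30, 30, 0)
  gmE <- oc$gm
  post <- genotypeProbs(inferGenotypes(oc$ac, gmE,
                                       hmmParams(errorRate = 0)))
  expect_gt(post$pNN[1, 1], 0.999)
  ocC <- oneCellCounts(0, 30, 0)
  postC <- genotypeProbs(inferGenotypes(ocC$ac, ocC$gm,
                                        hmmParams(errorRate = 0)))
  expect_gt(postC$pCC[1, 1], 0.999)
})

test_that("the unique-genotype expectation matches its closed form", {
  expect_equal(expectedUniqueGenotypes(1, 5), 1)
  expect_equal(expectedUniqueGenotypes(1, 1e6), 1)
  # decreasing in C/I pressure
  expect_gt(expectedUniqueGenotypes(100, 1e6),
            expectedUniqueGenotypes(100, 50))
})

test_that("genotype collisions are counted from dosage correlations", {
  set.seed(71)
  dos <- matrix(runif(60 * 40), nrow = 60)   # sites x cells, independent
  expect_equal(countGenotypeCollisions(dos), 0L)
  # plant k duplicated pairs: each duplicate correlates ~1 with its twin
  k <- 3
  dup <- dos[, 1:k]
  planted <- cbind(dos, dup + matrix(rnorm(60 * k, 0, 1e-4), 60))
  expect_gte(countGenotypeCollisions(planted), 2 * k)
  # identical pair: both counted
  two <- cbind(dos[, 1], dos[, 1])
  expect_equal(countGenotypeCollisions(two), 2L)
  # constant cells are excluded with a message
  cst <- cbind(dos, rep(0.5, 60))
  expect_message(countGenotypeCollisions(cst), "constant")
})

test_that("parental assignment follows the 50-count support rule", {
  expect_equal(assignParental(120, 3), "N2")
  expect_equal(assignParental(3, 120), "CB4856")
  expect_equal(assignParental(60, 55), "unassigned")
  expect_equal(assignParental(49, 0), "unassigned")
  expect_equal(assignParental(50, 49), "N2")  # boundary: >= 50 and < 50
  expect_equal(assignParental(c(120, 60, 49), c(3, 55, 0)),
               c("N2", "unassigned", "unassigned"))
})
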