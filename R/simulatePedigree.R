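## Pedigree simulation for an obligate-outcrossing intercross.
##
## Founders are pure-strain N2 hermaphrodites crossed to pure-strain CB
## males (the direction used to seed the segregant pool). Each subsequent
## generation is produced by random mating of hermaphrodites to males;
## selfing is impossible because every brood requires one parent of each
## sex. Males are X0: sperm carries the paternal X (daughters) or no X
## (sons), so hermaphrodite offspring receive one maternal recombinant X
## plus the paternal X, and male offspring receive a maternal recombinant
## X only.
##
## A chromosome homolog is a piecewise-constant allele function on the cM
## interval [0, L]: `breaks` are the ascending internal breakpoints and
## `alleles` the founder allele (0 = N2, 1 = CB) of each segment. Meiosis
## places crossovers as a Poisson process on the cM scale (no
## interference), i.e. a Haldane-style map.

.newHomolog <- function(allele)
  list(breaks = numeric(0), alleles = allele)

.evalHomolog <- function(h, pos)
  h$alleles[findInterval(pos, h$breaks) + 1L]

# recombinant gamete from homolog pair (h1, h2) on a chromosome of L cM
.gamete <- function(h1, h2, L) {
  k <- stats::rpois(1L, L / 100)
  xo <- if (k > 0) sort(stats::runif(k, 0, L)) else numeric(0)
  first <- sample.int(2L, 1L)
  brks <- sort(unique(c(xo, h1$breaks, h2$breaks)))
  bounds <- c(0, brks, L)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  src <- 1L + (first - 1L + findInterval(mids, xo)) %% 2L
  al <- ifelse(src == 1L, .evalHomolog(h1, mids), .evalHomolog(h2, mids))
  keep <- which(diff(al) != 0)
  list(breaks = brks[keep], alleles = al[c(keep, length(al))],
       nxo = k)
}

#' Simulate an obligate-outcrossing intercross pedigree
#'
#' Produces the genotypes and sexes of the final-generation individuals of
#' an F_g intercross founded by N2 hermaphrodites mated to CB males.
#' Autosomal meioses place crossovers as a Poisson process on the cM scale
#' (no interference). X transmission follows X0 sex determination:
#' hermaphrodite offspring receive one maternal recombinant X and the
#' paternal X; male offspring are hemizygous for a maternal recombinant X.
#'
#' The population is kept at `nIndividuals(design)` individuals in every
#' generation; parents are drawn with replacement from the hermaphrodites
#' and males of the previous generation.
#'
#' @param design a [CrossDesign-class]; `generations` must be at least 2.
#' @param genome a [SimGenome-class].
#' @param seed RNG seed.
#' @return A [SimTruth-class] with `genotypes` (individuals x sites, CB
#'   allele count; hemizygous male X stored as 0/2) and `sex` filled in.
#'   The eQTL architecture slots are empty until [plantEqtlArchitecture()]
#'   is called.
#' @seealso [plantEqtlArchitecture()], [sampleCells()],
#'   [simulateAlleleCounts()], [simulateExpression()]
#' @export
simulatePedigree <- function(design, genome, seed = 1) {
  stopifnot(is(design, "CrossDesign"), is(genome, "SimGenome"))
  if (design@generations < 2)
    stop("generations must be >= 2: an F1 has no recombinant pool")
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)

  I <- nIndividuals(design)
  chroms <- genome@chromosomes
  gm <- geneticMap(genome@map, scaleFactor = 1)
  spans <- chromosomeSpans(gm)[chroms$chrom]
  if (!all(is.finite(spans)) || any(spans <= 0))
    stop("non-finite or non-positive map length")
  nC <- nrow(chroms)
  xIdx <- which(chroms$is_x)

  # founder generation: hermaphrodites pure N2 (allele 0), males pure CB
  mkFounder <- function(sex) {
    allele <- if (sex == "hermaphrodite") 0L else 1L
    chromList <- lapply(seq_len(nC), function(ci) {
      if (ci %in% xIdx && sex == "male")
        list(mat = .newHomolog(allele), pat = NULL)
      else
        list(mat = .newHomolog(allele), pat = .newHomolog(allele))
    })
    list(sex = sex, chroms = chromList)
  }
  nh <- max(2L, ceiling(I / 2)); nm <- max(2L, I - nh)
  pop <- c(replicate(nh, mkFounder("hermaphrodite"), simplify = FALSE),
           replicate(nm, mkFounder("male"), simplify = FALSE))

  for (gen in seq_len(design@generations)) {
    sexes <- vapply(pop, `[[`, "", "sex")
    moms <- which(sexes == "hermaphrodite")
    dads <- which(sexes == "male")
    if (!length(moms) || !length(dads))
      stop("generation ", gen - 1L, " has zero individuals of one sex; ",
           "increase the population size")
    pop <- lapply(seq_len(I), function(i) {
      mom <- pop[[moms[sample.int(length(moms), 1L)]]]
      dad <- pop[[dads[sample.int(length(dads), 1L)]]]
      sex <- if (stats::runif(1) < 0.5) "hermaphrodite" else "male"
      chromList <- lapply(seq_len(nC), function(ci) {
        L <- spans[ci]
        if (ci %in% xIdx) {
          matX <- .gamete(mom$chroms[[ci]]$mat, mom$chroms[[ci]]$pat, L)
          if (sex == "hermaphrodite")
            list(mat = matX, pat = dad$chroms[[ci]]$mat)
          else
            list(mat = matX, pat = NULL)
        } else {
          list(mat = .gamete(mom$chroms[[ci]]$mat, mom$chroms[[ci]]$pat, L),
               pat = .gamete(dad$chroms[[ci]]$mat, dad$chroms[[ci]]$pat, L))
        }
      })
      list(sex = sex, chroms = chromList)
    })
  }

  sites <- genome@sites
  siteCm <- interpolateMap(gm, sites$chrom, sites$pos)
  siteCmByChrom <- split(siteCm, factor(sites$chrom, levels = chroms$chrom))
  siteIdxByChrom <- split(seq_len(nrow(sites)),
                          factor(sites$chrom, levels = chroms$chrom))

  G <- matrix(0L, nrow = I, ncol = nrow(sites))
  for (i in seq_len(I)) {
    ind <- pop[[i]]
    for (ci in seq_len(nC)) {
      idx <- siteIdxByChrom[[ci]]
      if (!length(idx)) next
      pos <- siteCmByChrom[[ci]]
      matAl <- .evalHomolog(ind$chroms[[ci]]$mat, pos)
      patAl <- if (is.null(ind$chroms[[ci]]$pat)) matAl
               else .evalHomolog(ind$chroms[[ci]]$pat, pos)
      G[i, idx] <- matAl + patAl
    }
  }

  new("SimTruth",
      design = design, genome = genome, genotypes = G,
      sex = vapply(pop, `[[`, "", "sex"),
      plantedCis = data.frame(gene = character(), site = integer(),
                              effect = numeric()),
      plantedTrans = data.frame(gene = character(), site = integer(),
                                effect = numeric(), hotspot = integer()),
      baseline = numeric(0), theta = numeric(0),
      batchEffects = matrix(numeric(0), 0, 0),
      cellTypeEffects = matrix(numeric(0), 0, 0),
      cellTypes = character(0), seed = as.integer(seed))
}
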