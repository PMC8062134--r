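#' Build a simulated genome layout
#'
#' Constructs a [SimGenome-class] emulating a compact nematode genome: five
#' autosomes and one X chromosome with physical sizes in the 14-21 Mb range
#' and a linear genetic map (default 50 cM per chromosome, 300 cM total).
#' Variant sites and genes are placed uniformly at random along the
#' chromosomes, with counts proportional to physical length.
#'
#' @param nSites total number of biallelic transcribed variant sites.
#' @param nGenes total number of genes.
#' @param chromosomes optional data.frame with columns `chrom`, `length_bp`,
#'   `is_x`; defaults to a six-chromosome layout (I-V plus X).
#' @param chromCm genetic length per chromosome in cM (recycled).
#' @param seed RNG seed for site/gene placement.
#' @return A [SimGenome-class].
#' @examples
#' g <- simGenome(nSites = 300, nGenes = 50, seed = 1)
#' g
#' @export
simGenome <- function(nSites = 2000, nGenes = 200, chromosomes = NULL,
                      chromCm = 50, seed = 1) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(
      chrom = c("I", "II", "III", "IV", "V", "X"),
      length_bp = c(15.1e6, 15.3e6, 13.8e6, 17.5e6, 20.9e6, 17.7e6),
      is_x = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    )
  }
  stopifnot(nSites >= nrow(chromosomes), nGenes >= 1)
  chromCm <- rep_len(chromCm, nrow(chromosomes))
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  map <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    data.frame(chrom = chromosomes$chrom[i],
               bp = c(1, chromosomes$length_bp[i]),
               cM = c(0, chromCm[i]))
  }))

  # at least one site per chromosome, remainder proportional to length
  prop <- chromosomes$length_bp / sum(chromosomes$length_bp)
  nPer <- pmax(1L, as.integer(round(prop * nSites)))
  bases <- c("A", "C", "G", "T")
  sites <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    pos <- sort(sample.int(chromosomes$length_bp[i] - 2L, nPer[i])) + 1L
    ref <- sample(bases, nPer[i], replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    data.frame(chrom = chromosomes$chrom[i], pos = pos, ref = ref,
               alt = alt)
  }))
  rownames(sites) <- NULL

  nG <- pmax(1L, as.integer(round(prop * nGenes)))
  genes <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    pos <- sort(sample.int(chromosomes$length_bp[i] - 2L, nG[i])) + 1L
    data.frame(chrom = chromosomes$chrom[i], pos = pos)
  }))
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(nrow(genes))),
                      chrom = genes$chrom, pos = genes$pos)

  new("SimGenome", chromosomes = chromosomes, map = map, sites = sites,
      genes = genes)
}

# run code under a temporary RNG state; returns a restore function
.with_seed <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
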