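#' Interpolate genetic map positions for variant sites
#'
#' Linearly interpolates cM positions from the map anchors to arbitrary bp
#' positions. Sites beyond the terminal anchors are extrapolated with the
#' slope of the terminal segment (and a message is emitted, since such sites
#' lie outside the mapped region).
#'
#' The returned positions are raw (unscaled) cM; the map's `scaleFactor` is
#' applied to *distances between adjacent sites* when building transition
#' probabilities, not to the positions themselves. See [scaledGaps()].
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome of each site.
#' @param bp physical position of each site.
#' @return numeric vector of cM positions, parallel to `bp`.
#' @examples
#' gm <- geneticMap(data.frame(chrom = "I", bp = c(0, 2e6), cM = c(0, 2)))
#' interpolateMap(gm, "I", 1e6)  # 1 cM, midway between the anchors
#' @export
interpolateMap <- function(map, chrom, bp) {
  stopifnot(is(map, "GeneticMap"), length(chrom) == length(bp))
  out <- numeric(length(bp))
  for (cc in unique(chrom)) {
    a <- map@anchors[map@anchors$chrom == cc, ]
    if (nrow(a) < 2)
      stop("chromosome ", cc, " has fewer than 2 map anchors")
    idx <- which(chrom == cc)
    x <- bp[idx]
    if (any(x < min(a$bp) | x > max(a$bp)))
      message("interpolateMap: sites beyond map anchors on ", cc,
              "; extrapolating with the terminal segment slope")
    # rule = 2 clamps; replace the clamp by linear extrapolation of the
    # terminal segments so cM keeps increasing past the last anchor
    cm <- stats::approx(a$bp, a$cM, xout = x, rule = 2, ties = "ordered")$y
    lo <- x < a$bp[1]
    hi <- x > a$bp[nrow(a)]
    if (any(lo)) {
      sl <- (a$cM[2] - a$cM[1]) / (a$bp[2] - a$bp[1])
      cm[lo] <- a$cM[1] + (x[lo] - a$bp[1]) * sl
    }
    if (any(hi)) {
      n <- nrow(a)
      sl <- (a$cM[n] - a$cM[n - 1]) / (a$bp[n] - a$bp[n - 1])
      cm[hi] <- a$cM[n] + (x[hi] - a$bp[n]) * sl
    }
    out[idx] <- cm
  }
  out
}

#' Scaled cM gaps between adjacent sites
#'
#' Interpolates cM positions for an ordered set of sites and returns the
#' between-adjacent-site distances multiplied by the map's scale factor.
#' These scaled gaps parameterize the HMM transition matrices.
#'
#' @param map a [GeneticMap-class].
#' @param chrom,bp ordered site coordinates (single chromosome expected).
#' @return numeric vector of length `length(bp) - 1` of scaled cM gaps.
#' @export
scaledGaps <- function(map, chrom, bp) {
  cm <- interpolateMap(map, chrom, bp)
  if (is.unsorted(cm)) stop("sites must be ordered by position")
  diff(cm) * map@scaleFactor
}

#' Total (scaled) map length per chromosome
#' @param map a [GeneticMap-class].
#' @param scaled multiply spans by the map's scale factor? Default FALSE.
#' @return named numeric vector of cM spans.
#' @export
chromosomeSpans <- function(map, scaled = FALSE) {
  sp <- vapply(split(map@anchors$cM, map@anchors$chrom),
               function(x) max(x) - min(x), numeric(1))
  sp <- sp[unique(map@anchors$chrom)]
  if (scaled) sp * map@scaleFactor else sp
}
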