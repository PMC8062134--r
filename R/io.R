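#' @importFrom Matrix readMM writeMM
NULL

## Writers ------------------------------------------------------------------

#' Write variant sites as a minimal VCF
#'
#' Biallelic SNV sites only: CHROM, POS, ID (`.`), REF, ALT, QUAL (`.`),
#' FILTER (`PASS`), INFO (`.`). Positions are 1-based inclusive.
#'
#' @param sites data.frame with `chrom`, `pos` and optionally `ref`, `alt`.
#' @param path output path.
#' @export
writeVcfSites <- function(sites, path) {
  ref <- if ("ref" %in% names(sites)) sites$ref else "A"
  alt <- if ("alt" %in% names(sites)) sites$alt else "T"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                     sites$chrom, as.integer(sites$pos), ref, alt), con)
  invisible(path)
}

#' Write an AlleleCounts object to disk
#'
#' Produces the four files of the allele-counting layout: a sites VCF, two
#' MatrixMarket triplet matrices (sites in rows, cells in columns) with
#' the UMI counts supporting each parental allele, and a barcodes file.
#'
#' @param ac an [AlleleCounts-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeAlleleCounts <- function(ac, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             ref = file.path(dir, "n2_counts.mtx"),
             alt = file.path(dir, "cb_counts.mtx"),
             barcodes = file.path(dir, "barcodes.tsv"))
  writeVcfSites(siteInfo(ac), paths["vcf"])
  Matrix::writeMM(n2Counts(ac), paths["ref"])
  Matrix::writeMM(cbCounts(ac), paths["alt"])
  writeLines(colnames(ac), paths["barcodes"])
  paths
}

#' Read allele counts from a VCF plus two MatrixMarket matrices
#'
#' Reads the layout produced by per-cell allele counting of droplet BAMs
#' (and by [writeAlleleCounts()]): a VCF of biallelic sites and two sparse
#' matrices of UMI counts, sites in rows and cells in columns. Sites are
#' sorted by (chromosome, position) with the same permutation applied to
#' both matrices. Dimension mismatches between the VCF, the matrices and
#' the barcodes are an error naming both shapes.
#'
#' @param vcf path to the sites VCF.
#' @param refMtx,altMtx paths to the N2- and CB-supporting count matrices.
#' @param barcodes path to the barcodes file (one per matrix column).
#' @param siteWhitelist optional logical or integer vector selecting sites
#'   to keep (e.g. sites in genes with positive ambient-corrected counts).
#' @return An [AlleleCounts-class].
#' @export
readAlleleCounts <- function(vcf, refMtx, altMtx, barcodes,
                             siteWhitelist = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT)
  n2 <- methods::as(Matrix::readMM(refMtx), "CsparseMatrix")
  cb <- methods::as(Matrix::readMM(altMtx), "CsparseMatrix")
  bc <- readLines(barcodes)
  if (nrow(n2) != nrow(sites) || !all(dim(n2) == dim(cb)) ||
      ncol(n2) != length(bc))
    stop("dimension mismatch: VCF has ", nrow(sites), " sites; matrices ",
         nrow(n2), "x", ncol(n2), " and ", nrow(cb), "x", ncol(cb),
         "; ", length(bc), " barcodes")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  ac <- AlleleCounts(n2[ord, , drop = FALSE], cb[ord, , drop = FALSE],
                     sites, barcodes = bc)
  if (!is.null(siteWhitelist)) ac <- ac[siteWhitelist, ]
  message("readAlleleCounts: ", nrow(ac), " sites x ", ncol(ac),
          " cells; total counts ",
          sum(n2Counts(ac)) + sum(cbCounts(ac)))
  ac
}

#' Write expression counts plus metadata
#'
#' Writes the counts as a MatrixMarket matrix (genes in rows, cells in
#' columns), the gene table as TSV (`gene`, `chrom`, `pos`), and the cell
#' metadata as TSV (`cell`, `batch`, plus any further `colData` columns).
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param dir output directory.
#' @return named character vector of paths.
#' @export
writeExpression <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mtx = file.path(dir, "expression.mtx"),
             genes = file.path(dir, "genes.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  Matrix::writeMM(methods::as(
    SummarizedExperiment::assay(sce, "counts"), "CsparseMatrix"),
    paths["mtx"])
  utils::write.table(
    as.data.frame(SummarizedExperiment::rowData(sce)), paths["genes"],
    sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd <- cd[, !(names(cd) %in% c("total_umis", "log_total")), drop = FALSE]
  utils::write.table(cd, paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Read expression counts plus metadata
#'
#' Rebuilds the SingleCellExperiment from the [writeExpression()] layout.
#' Total UMIs and their log are recomputed from the counts. Metadata rows
#' must match the matrix columns exactly; a missing `batch` column or a
#' cell-count mismatch is an error.
#'
#' @param mtx path to the counts MatrixMarket file.
#' @param genesTsv path to the gene table.
#' @param metadataTsv path to the cell metadata.
#' @return A SingleCellExperiment.
#' @export
readExpression <- function(mtx, genesTsv, metadataTsv) {
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- utils::read.delim(genesTsv, stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadataTsv, stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(counts))
    stop("metadata has ", nrow(meta), " cells but the matrix has ",
         ncol(counts), " columns")
  if (nrow(genes) != nrow(counts))
    stop("gene table has ", nrow(genes), " genes but the matrix has ",
         nrow(counts), " rows")
  if (!"batch" %in% names(meta)) stop("metadata lacks a batch column")
  dimnames(counts) <- list(genes$gene, meta$cell)
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cells with zero total UMIs present")
  meta$batch <- factor(meta$batch)
  meta$total_umis <- total
  meta$log_total <- log(total)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(genes),
    colData = DataFrame(meta))
}

#' Write / read a genetic map as TSV
#'
#' Columns `chrom`, `bp`, `cM`.
#' @param map a [GeneticMap-class].
#' @param path file path.
#' @export
writeGeneticMap <- function(map, path) {
  utils::write.table(map@anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneticMap
#' @param scaleFactor scale factor for the map read back (default 0.4).
#' @export
readGeneticMap <- function(path, scaleFactor = 0.4) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  geneticMap(a, scaleFactor = scaleFactor)
}

#' Write a full simulation to disk
#'
#' Writes everything the pipeline consumes — allele counts (VCF + MTX +
#' barcodes), expression (MTX + genes + metadata), the genetic map — plus
#' the ground-truth tables (planted cis and trans effects, true genotypes
#' summarized as individual assignments per cell) for recovery analyses.
#'
#' @param truth a [SimTruth-class].
#' @param cells cell table from [sampleCells()].
#' @param ac an [AlleleCounts-class].
#' @param sce expression SingleCellExperiment.
#' @param dir output directory.
#' @return named character vector of paths.
#' @export
writeSimulation <- function(truth, cells, ac, sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- writeAlleleCounts(ac, dir)
  p2 <- writeExpression(sce, dir)
  mapPath <- file.path(dir, "genetic_map.tsv")
  writeGeneticMap(geneticMap(truth@genome@map), mapPath)
  cisPath <- file.path(dir, "truth_cis.tsv")
  utils::write.table(truth@plantedCis, cisPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  transPath <- file.path(dir, "truth_trans.tsv")
  utils::write.table(truth@plantedTrans, transPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(p1, p2, map = mapPath, truth_cis = cisPath, truth_trans = transPath)
}
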