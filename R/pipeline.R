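#' Read a pipeline run configuration
#'
#' The configuration is a flat YAML file with a `schema` version field,
#' input paths, an output directory, a seed, and per-stage parameter
#' blocks mirroring the package defaults. Missing parameters fall back to
#' the defaults documented on the corresponding functions.
#'
#' @param path YAML file path.
#' @return list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema)) stop("config lacks a schema version field")
  defaults <- list(
    seed = 1L,
    outdir = "sceqtl_out",
    scale_factor = 0.4,
    error_rate = 0.002,
    fdr = 0.1,
    n_perm = 10,
    min_cells = 20,
    r_max = 0.9999,
    bin_cm = 5,
    alpha = 0.05,
    cis_pad_bp = 1e6,
    run_trans = FALSE,
    run_classifier = TRUE
  )
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = c("RunConfig", "list"))
}

#' Run the full eQTL pipeline
#'
#' Executes genotype inference, per-cell-type cis mapping with permutation
#' FDR, optionally the genome-wide trans scan and hotspot detection, and
#' the cell-type classifier, from the file layout described in
#' [readAlleleCounts()] and [readExpression()]. Every stage logs the
#' parameters in use; outputs are deterministic given the seed.
#'
#' Required config fields: `vcf`, `ref_mtx`, `alt_mtx`, `barcodes`,
#' `expression_mtx`, `genes_tsv`, `metadata_tsv`, `map_tsv`, `outdir`.
#'
#' @param config a `"RunConfig"` from [readRunConfig()], or a list with
#'   the same fields.
#' @param dryRun print the stage plan and return without computing.
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
runPipeline <- function(config, dryRun = FALSE) {
  stages <- c("genotype", "map",
              if (isTRUE(config$run_trans)) c("trans", "hotspots"),
              if (isTRUE(config$run_classifier)) "classify")
  if (dryRun) {
    cat("pipeline plan:", paste(stages, collapse = " -> "), "\n")
    cat("outdir:", config$outdir, " seed:", config$seed, "\n")
    return(invisible(list(stages = stages)))
  }
  for (f in c("vcf", "ref_mtx", "alt_mtx", "barcodes", "expression_mtx",
              "genes_tsv", "metadata_tsv", "map_tsv")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("config file missing or absent on disk: ", f, " = ",
           if (is.null(config[[f]])) "<unset>" else config[[f]])
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = config)

  message("[genotype] scale ", config$scale_factor, ", error rate ",
          config$error_rate)
  ac <- readAlleleCounts(config$vcf, config$ref_mtx, config$alt_mtx,
                         config$barcodes)
  map <- readGeneticMap(config$map_tsv,
                        scaleFactor = config$scale_factor)
  post <- inferGenotypes(ac, map,
                         hmmParams(errorRate = config$error_rate))
  out$posteriors <- post
  utils::write.table(
    data.frame(siteInfo(ac),
               round(dosage(post), 6), check.names = FALSE),
    file.path(config$outdir, "dosage.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  sce <- readExpression(config$expression_mtx, config$genes_tsv,
                        config$metadata_tsv)
  markers <- pruneMarkers(post, rMax = config$r_max, map = map)
  types <- sort(unique(SummarizedExperiment::colData(sce)$cell_type))

  message("[map] cis scan, FDR ", config$fdr, ", ", config$n_perm,
          " permutations, min cells ", config$min_cells)
  cisTabs <- list()
  for (ct in types) {
    nCt <- sum(SummarizedExperiment::colData(sce)$cell_type == ct)
    if (nCt < config$min_cells) {
      message("[map] skipping ", ct, ": only ", nCt, " cells")
      next
    }
    cis <- tryCatch(
      cisScan(sce, markers, cellType = ct,
              minCells = config$min_cells),
      error = function(e) stop("stage map failed for cell type ", ct,
                               ": ", conditionMessage(e)))
    if (!nrow(cis)) next
    cis <- cisPermutationFdr(sce, markers, cis, cellType = ct,
                             minCells = config$min_cells,
                             nPerm = config$n_perm,
                             seed = config$seed)$result
    cisTabs[[ct]] <- cis
  }
  cisAll <- do.call(rbind, cisTabs)
  if (!is.null(cisAll)) {
    cisAll <- cisAll[order(cisAll$cell_type, cisAll$gene_chrom,
                           cisAll$gene_pos), ]
    utils::write.table(cisAll, file.path(config$outdir, "eqtl_cis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out$cis <- cisAll

  if (isTRUE(config$run_trans)) {
    message("[trans] genome-wide scan and hotspots, bin ",
            config$bin_cm, " cM, alpha ", config$alpha)
    transTabs <- list()
    for (ct in names(cisTabs)) {
      thetas <- stats::setNames(cisTabs[[ct]]$theta, cisTabs[[ct]]$gene)
      tr <- transScan(sce, markers, cellType = ct, thetas = thetas,
                      minCells = config$min_cells)
      tr <- transPermutationFdr(sce, markers, tr, cellType = ct,
                                minCells = config$min_cells,
                                nPerm = config$n_perm,
                                seed = config$seed)$peaks
      transTabs[[ct]] <- tr
    }
    transAll <- do.call(rbind, transTabs)
    if (!is.null(transAll)) {
      transAll <- transAll[order(transAll$cell_type, transAll$chrom,
                                 transAll$pos), ]
      utils::write.table(transAll,
                         file.path(config$outdir, "eqtl_trans.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bins <- binGenome(map, widthCm = config$bin_cm)
      lk <- countTransLinkages(transAll, bins, fdrMax = config$fdr,
                               cisPadBp = config$cis_pad_bp, map = map)
      hs <- detectHotspots(lk, alpha = config$alpha)
      utils::write.table(hs, file.path(config$outdir, "hotspots.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$hotspots <- hs
    }
    out$trans <- transAll
  }

  if (isTRUE(config$run_classifier)) {
    message("[classify] C = ", classifierConfig()$C)
    cfg <- classifierConfig()
    pp <- preprocessClassifier(sce, cfg)
    labels <- SummarizedExperiment::colData(sce)$cell_type
    probs <- crossValProbabilities(pp$features, labels, cfg,
                                   seed = config$seed)
    calls <- callCells(probs, cfg)
    callTab <- data.frame(cell = colnames(sce), round(probs, 6),
                          label = calls$label, check.names = FALSE)
    utils::write.table(callTab,
                       file.path(config$outdir, "cell_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$calls <- callTab
  }
  invisible(out)
}
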