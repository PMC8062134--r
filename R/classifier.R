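#' Configuration of the cell-type classifier
#'
#' Bundles the preprocessing and model constants of the penalized
#' multinomial cell-type classifier: library-size normalization target,
#' highly-variable-gene (HVG) mean window and dispersion floor, z-score
#' clip, the inverse regularization strength `C` of the L2-penalized
#' multinomial logistic regression, cross-validation folds, and the
#' doublet / low-quality probability rules.
#'
#' @param targetSum per-cell normalization target (default 10000).
#' @param hvgMeanRange mean-expression window for HVG selection (default
#'   `c(0.0125, 3)`, on normalized log values).
#' @param hvgMinDispersion minimum dispersion (variance/mean of the
#'   normalized log values, per gene) for HVGs (default 0.5).
#' @param scaleClip upper clip for z-scored values (default 20).
#' @param C inverse regularization strength (default 7.74e-4). Smaller is
#'   stronger; the ridge penalty weight is `1 / (C * nCells)`.
#' @param cvFolds stratified cross-validation folds (default 5).
#' @param doubletProb a cell with more than one class probability above
#'   this is a doublet (default 0.2).
#' @param lowqProb a non-doublet whose best class probability falls below
#'   this is low quality (default 0.4).
#' @param minCellsPerGene genes in fewer cells are removed (default 10).
#' @return list of class `"ClassifierConfig"`.
#' @export
classifierConfig <- function(targetSum = 1e4,
                             hvgMeanRange = c(0.0125, 3),
                             hvgMinDispersion = 0.5,
                             scaleClip = 20,
                             C = 7.74e-4,
                             cvFolds = 5,
                             doubletProb = 0.2,
                             lowqProb = 0.4,
                             minCellsPerGene = 10) {
  stopifnot(doubletProb > 0, doubletProb < lowqProb, lowqProb < 1,
            scaleClip > 0, C > 0, cvFolds >= 2)
  structure(list(targetSum = targetSum, hvgMeanRange = hvgMeanRange,
                 hvgMinDispersion = hvgMinDispersion,
                 scaleClip = scaleClip, C = C, cvFolds = cvFolds,
                 doubletProb = doubletProb, lowqProb = lowqProb,
                 minCellsPerGene = minCellsPerGene),
            class = "ClassifierConfig")
}

#' Preprocess counts for the cell-type classifier
#'
#' Removes genes expressed in fewer than `minCellsPerGene` cells, scales
#' each cell to `targetSum` total counts, log(1+x)-transforms, selects
#' highly variable genes by a mean window and a dispersion floor
#' (dispersion = variance/mean of the normalized log values per gene,
#' computed before z-scoring), z-scores each HVG across cells, and clips
#' values above `scaleClip`.
#'
#' When `stats` (from a previous call, i.e. the training data) is
#' supplied, its gene set, HVG list, means and SDs are reused so that new
#' cells are projected into the training feature space.
#'
#' @param counts genes x cells count matrix (or SummarizedExperiment with
#'   a `counts` assay).
#' @param config a [classifierConfig()].
#' @param stats optional preprocessing statistics to reuse.
#' @return list with `features` (cells x HVGs, scaled and clipped),
#'   `hvg` (gene names), `stats` (reusable statistics).
#' @export
preprocessClassifier <- function(counts, config = classifierConfig(),
                                 stats = NULL) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (min(counts) < 0) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  if (is.null(stats)) {
    keepGene <- rowSums(counts > 0) >= config$minCellsPerGene
  } else {
    keepGene <- rownames(counts) %in% stats$genes
  }
  counts <- counts[keepGene, , drop = FALSE]
  norm <- sweep(counts, 2, config$targetSum / tot, "*")
  lg <- log1p(norm)
  if (is.null(stats)) {
    m <- rowMeans(lg)
    v <- apply(lg, 1, stats::var)
    disp <- ifelse(m > 0, v / m, 0)
    hvg <- rownames(lg)[m > config$hvgMeanRange[1] &
                          m < config$hvgMeanRange[2] &
                          disp >= config$hvgMinDispersion]
    if (!length(hvg)) stop("no highly variable genes selected")
    sub <- lg[hvg, , drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    sd[sd == 0] <- 1
    stats <- list(genes = rownames(counts), hvg = hvg, mean = mu, sd = sd)
  }
  sub <- lg[stats$hvg, , drop = FALSE]
  z <- (sub - stats$mean) / stats$sd
  z[z > config$scaleClip] <- config$scaleClip
  list(features = t(z), hvg = stats$hvg, stats = stats)
}

#' Fit the penalized multinomial cell-type classifier
#'
#' L2-penalized (ridge) multinomial logistic regression on the scaled
#' feature matrix, at the fixed penalty implied by the config's inverse
#' regularization strength `C` (`lambda = 1 / (C * nCells)` in the
#' `glmnet` parameterization of the ridge weight).
#'
#' @param features cells x genes matrix from [preprocessClassifier()].
#' @param labels cell-type label per cell (>= 2 classes, each with at
#'   least `cvFolds` cells).
#' @param config a [classifierConfig()].
#' @return list of class `"CellTypeClassifier"`: `fit` (glmnet object),
#'   `lambda`, `classes`, `config`.
#' @export
fitCellTypeClassifier <- function(features, labels,
                                  config = classifierConfig()) {
  labels <- factor(labels)
  small <- table(labels) < config$cvFolds
  if (nlevels(labels) < 2 || any(small))
    stop("each class needs at least ", config$cvFolds, " cells; short: ",
         paste(names(which(small)), collapse = ", "))
  lambda <- 1 / (config$C * nrow(features))
  fit <- glmnet::glmnet(features, labels, family = "multinomial",
                        alpha = 0, lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, classes = levels(labels),
                 config = config),
            class = "CellTypeClassifier")
}

#' Class probabilities from a fitted classifier
#' @param model a `"CellTypeClassifier"`.
#' @param features cells x genes matrix in the training feature space.
#' @return matrix cells x classes of probabilities (rows sum to one).
#' @export
predictCellTypeProbs <- function(model, features) {
  p <- stats::predict(model$fit, features, type = "response")[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                   dimnames = list(NULL, names(p)))
  p
}

#' Cross-validated class probabilities
#'
#' Produces an out-of-fold probability for every training cell using
#' stratified folds: each cell's probabilities come from the model fitted
#' with its fold held out, so self-classification does not inflate
#' confidence.
#'
#' @param features cells x genes matrix.
#' @param labels cell-type labels.
#' @param config a [classifierConfig()].
#' @param seed RNG seed for the fold assignment.
#' @return matrix cells x classes of out-of-fold probabilities.
#' @export
crossValProbabilities <- function(features, labels,
                                  config = classifierConfig(), seed = 1) {
  labels <- factor(labels)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  n <- nrow(features)
  fold <- integer(n)
  for (cl in levels(labels)) {
    pos <- which(labels == cl)
    fold[pos] <- sample(rep_len(seq_len(config$cvFolds), length(pos)))
  }
  probs <- matrix(NA_real_, n, nlevels(labels),
                  dimnames = list(rownames(features), levels(labels)))
  for (f in seq_len(config$cvFolds)) {
    tr <- fold != f
    model <- fitCellTypeClassifier(features[tr, , drop = FALSE],
                                   labels[tr], config)
    p <- predictCellTypeProbs(model, features[!tr, , drop = FALSE])
    probs[!tr, colnames(p)] <- p
  }
  probs
}

#' Call cells from class probabilities
#'
#' Applies the decision rules in order: a cell with more than one class
#' probability above `doubletProb` is a doublet; otherwise a cell whose
#' maximal probability is below `lowqProb` is low quality; otherwise the
#' cell is assigned its argmax class.
#'
#' @param probs cells x classes probability matrix.
#' @param config a [classifierConfig()].
#' @return data.frame with `label` (class name, `"doublet"` or
#'   `"low_quality"`) and `max_prob`.
#' @examples
#' p <- rbind(c(0.5, 0.3, 0.2), c(0.95, 0.03, 0.02), c(0.39, 0.31, 0.30))
#' colnames(p) <- c("a", "b", "c")
#' callCells(p)$label  # doublet, a, doublet
#' @export
callCells <- function(probs, config = classifierConfig()) {
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  nHigh <- rowSums(probs > config$doubletProb)
  best <- max.col(probs, ties.method = "first")
  maxP <- probs[cbind(seq_len(nrow(probs)), best)]
  label <- colnames(probs)[best]
  label[maxP < config$lowqProb] <- "low_quality"
  label[nHigh >= 2] <- "doublet"
  data.frame(label = label, max_prob = maxP,
             row.names = rownames(probs))
}
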