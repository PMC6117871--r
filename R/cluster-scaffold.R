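#' Variable-gene selection fit
#'
#' Result of the log(CV) versus log(mean) procedure: a straight-line least
#' squares fit of log10 coefficient of variation on log10 mean over all
#' genes with positive mean, with genes ranked by their (positive)
#' residual above the line.
#'
#' @slot table data.frame with `gene`, `mean`, `cv`, `residual`, `selected`.
#' @slot slope,intercept numeric fit coefficients (log10 space).
#' @slot n integer number of genes selected.
#' @export
setClass("VariableGeneFit",
  representation(table = "data.frame", slope = "numeric",
                 intercept = "numeric", n = "integer"))

setMethod("show", "VariableGeneFit", function(object) {
  cat("VariableGeneFit:", object@n, "of", nrow(object@table),
      "eligible genes selected; log10(CV) =",
      signif(object@intercept, 3), "+", signif(object@slope, 3),
      "* log10(mean)\n")
})

#' Selected genes of a variable-gene fit
#' @param fit a [VariableGeneFit-class]
#' @return character vector of selected gene ids, highest residual first.
#' @export
selectedGenes <- function(fit) {
  stopifnot(is(fit, "VariableGeneFit"))
  tab <- fit@table[fit@table$selected, ]
  tab$gene[order(-tab$residual, tab$gene)]
}

#' Select highly variable genes by the CV-vs-mean procedure
#'
#' For every gene with positive mean across cells, computes the mean and
#' coefficient of variation (SD/mean, with an epsilon guard so
#' zero-variance genes get CV = eps rather than 0 before the log), fits
#' log10(CV) ~ log10(mean) by ordinary least squares, and selects the `n`
#' genes with the largest residuals. Deterministic; ties broken by gene id.
#'
#' @param m count container (raw or normalized counts).
#' @param n number of genes to select (default 1000).
#' @param eps guard added to CV before taking logs (default 1e-8).
#' @return a [VariableGeneFit-class].
#' @export
selectVariableGenes <- function(m, n = 1000, eps = 1e-8) {
  validateCountMatrix(m, allow_real = TRUE)
  if (ncol(m) < 2) stop("need at least 2 cells")
  x <- counts(m)
  mu <- Matrix::rowMeans(x)
  ex <- Matrix::rowMeans(x^2)
  sdev <- sqrt(pmax(0, (ex - mu^2) * ncol(m) / (ncol(m) - 1)))
  elig <- mu > 0
  if (n > sum(elig))
    stop("n = ", n, " exceeds the ", sum(elig), " genes with positive mean")
  cv <- ifelse(elig, pmax(sdev / ifelse(elig, mu, 1), eps), NA)
  lx <- log10(mu[elig]); ly <- log10(cv[elig])
  fit <- lm(ly ~ lx)
  resid <- rep(NA_real_, nrow(m))
  resid[elig] <- ly - (coef(fit)[1] + coef(fit)[2] * lx)
  ord <- order(-resid, rownames(m), na.last = TRUE)
  selected <- logical(nrow(m))
  selected[ord[seq_len(n)]] <- TRUE
  new("VariableGeneFit",
      table = data.frame(gene = rownames(m), mean = as.numeric(mu),
                         cv = as.numeric(cv), residual = resid,
                         selected = selected, stringsAsFactors = FALSE),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      n = as.integer(n))
}

#' Cluster cells (pluggable stand-in stage)
#'
#' The discrete clustering stage of the pipeline. The default implementation
#' log2(x+1)-transforms the counts of the selected variable genes, computes
#' the correlation distance between cells (1 - Pearson r), and cuts an
#' agglomerative Ward tree at `k` groups. It is deterministic and is an
#' explicit stand-in: downstream stages accept any
#' [ClusterAssignment-class], including one loaded from file
#' ([readClusterTable()]), so any clustering brand can be plugged in.
#'
#' @param m count container (normalized counts recommended).
#' @param fit a [VariableGeneFit-class] (or NULL to use all genes).
#' @param k number of clusters (1 <= k <= cells).
#' @param linkage hclust method (default "ward.D2").
#' @return a [ClusterAssignment-class] with labels `C1..Ck`.
#' @export
clusterCells <- function(m, fit = NULL, k, linkage = "ward.D2") {
  validateCountMatrix(m, allow_real = TRUE)
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(m)) stop("k = ", k, " exceeds ", ncol(m), " cells")
  genes <- if (is.null(fit)) rownames(m) else selectedGenes(fit)
  x <- log2(counts(m, dense = TRUE)[genes, , drop = FALSE] + 1)
  if (k == 1L)
    return(ClusterAssignment(setNames(rep("C1", ncol(m)), colnames(m))))
  cc <- suppressWarnings(cor(x))
  cc[!is.finite(cc)] <- 0
  d <- as.dist(1 - cc)
  h <- hclust(d, method = linkage)
  grp <- cutree(h, k = k)
  ClusterAssignment(setNames(paste0("C", grp), colnames(m)))
}

#' Merge fine clusters into coarser categories
#'
#' Relabels every cell through a fine-to-coarse label map (e.g. the merge
#' of 16 fine interneuron clusters into 6 main classes) and records the
#' operation in the assignment's merge history.
#'
#' @param a a [ClusterAssignment-class].
#' @param mapping named character vector: names are fine labels (must cover
#'   all labels present), values the merged labels.
#' @return the merged [ClusterAssignment-class].
#' @export
mergeClusters <- function(a, mapping) {
  lab <- clusterLabels(a)
  miss <- setdiff(unique(lab), names(mapping))
  if (length(miss))
    stop("unmapped fine label(s): ", paste(miss, collapse = ", "))
  out <- new("ClusterAssignment",
             labels = setNames(unname(mapping[lab]), names(lab)),
             hierarchy = c(a@hierarchy, list(mapping)))
  out
}

#' Cluster robustness report
#'
#' Held-out performance of a classifier trained to recognize cluster
#' labels: per-cluster precision and recall, and the K x K matrix of
#' probabilities that held-out cells of cluster j are classified as j'.
#'
#' @slot precision,recall named numeric per cluster (NA when undefined).
#' @slot confusion K x K matrix, rows (true clusters) summing to 1.
#' @slot trainFrac numeric; @slot seed integer.
#' @export
setClass("RobustnessReport",
  representation(precision = "numeric", recall = "numeric",
                 confusion = "matrix", trainFrac = "numeric",
                 seed = "integer"))

setValidity("RobustnessReport", function(object) {
  pr <- c(object@precision, object@recall)
  pr <- pr[!is.na(pr)]
  if (length(pr) && any(pr < 0 | pr > 1))
    return("precision/recall outside [0,1]")
  rs <- rowSums(object@confusion)
  if (length(rs) && max(abs(rs - 1)) > 1e-9)
    return("confusion rows must sum to 1")
  TRUE
})

setMethod("show", "RobustnessReport", function(object) {
  cat("RobustnessReport:", length(object@recall), "clusters;",
      "mean precision", round(100 * mean(object@precision, na.rm = TRUE)),
      "%, mean recall", round(100 * mean(object@recall, na.rm = TRUE)),
      paste0("% (held-out, ", 100 * object@trainFrac, "/",
             100 * (1 - object@trainFrac), " split)"), "\n")
})

#' Assess cluster robustness with a held-out classifier
#'
#' Splits the cells per cluster into training and test sets (stratified
#' 80/20 by default), trains a random-forest classifier on
#' log2(x+1)-transformed counts of the selected genes, and reports
#' per-cluster precision, recall and the held-out confusion probabilities.
#' With `repeats > 1` the split is redrawn and the reports averaged.
#'
#' @param m count container.
#' @param a a [ClusterAssignment-class]; every cluster needs >= 2 cells.
#' @param fit optional [VariableGeneFit-class] restricting the feature set.
#' @param train_frac fraction of each cluster used for training (0.8).
#' @param seed integer RNG seed (stratified split + forest).
#' @param repeats number of independent splits averaged (default 1).
#' @param ntree forest size (default 200).
#' @return a [RobustnessReport-class].
#' @export
assessRobustness <- function(m, a, fit = NULL, train_frac = 0.8, seed = 1,
                             repeats = 1, ntree = 200) {
  validateCountMatrix(m, allow_real = TRUE)
  cells <- checkAssignment(a, m, require_all = TRUE)
  lab <- factor(clusterLabels(a)[cells])
  sz <- table(lab)
  if (any(sz < 2))
    stop("singleton cluster(s): ",
         paste(names(sz)[sz < 2], collapse = ", "))
  genes <- if (is.null(fit)) rownames(m) else selectedGenes(fit)
  x <- t(log2(counts(m, dense = TRUE)[genes, cells, drop = FALSE] + 1))
  K <- nlevels(lab)
  acc <- list(prec = 0, rec = 0, conf = matrix(0, K, K))
  set.seed(seed)
  for (r in seq_len(repeats)) {
    tr <- unlist(lapply(levels(lab), function(j) {
      idx <- which(lab == j)
      ntr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
      sample(idx, ntr)
    }))
    te <- setdiff(seq_along(lab), tr)
    rf <- randomForest::randomForest(x[tr, , drop = FALSE], lab[tr],
                                     ntree = ntree)
    pred <- predict(rf, x[te, , drop = FALSE])
    cm <- table(true = lab[te], pred = factor(pred, levels = levels(lab)))
    rec <- diag(cm) / pmax(1, rowSums(cm))
    prec <- diag(cm) / ifelse(colSums(cm) > 0, colSums(cm), NA)
    conf <- cm / pmax(1, rowSums(cm))
    acc$prec <- acc$prec + prec / repeats
    acc$rec <- acc$rec + rec / repeats
    acc$conf <- acc$conf + unclass(conf) / repeats
  }
  conf <- acc$conf / rowSums(acc$conf)  # guard drift from averaging
  dimnames(conf) <- list(levels(lab), levels(lab))
  new("RobustnessReport",
      precision = setNames(as.numeric(acc$prec), levels(lab)),
      recall = setNames(as.numeric(acc$rec), levels(lab)),
      confusion = conf, trainFrac = train_frac, seed = as.integer(seed))
}

#' Dendrogram over cluster mean expression profiles
#'
#' Normalizes every cell to 10,000 total molecules, log2(x+1)-transforms,
#' averages the cells of each cluster, and builds a Ward linkage tree on
#' the correlation distance between cluster mean profiles.
#'
#' @param m count container (raw counts).
#' @param a a [ClusterAssignment-class] with >= 2 non-empty clusters.
#' @param target per-cell normalization total (default 10000).
#' @return an `hclust` tree whose leaves are cluster labels.
#' @export
clusterMeanDendrogram <- function(m, a, target = 10000) {
  validateCountMatrix(m)
  cells <- checkAssignment(a, m, require_all = TRUE)
  lab <- clusterLabels(a)[cells]
  labs <- sort(unique(lab))
  if (length(labs) < 2) stop("need at least 2 clusters")
  if (any(vapply(labs, function(j) sum(lab == j), integer(1)) == 0))
    stop("cluster with zero cells")
  norm <- normalizeTotal(m[, cells], target = target,
                         round_to_integer = FALSE)
  lx <- log2(counts(norm, dense = TRUE) + 1)
  means <- vapply(labs, function(j)
    rowMeans(lx[, lab == j, drop = FALSE]), numeric(nrow(lx)))
  cc <- suppressWarnings(cor(means))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  hclust(as.dist(1 - cc), method = "ward.D2")
}

#' Export a linkage tree as Newick text
#'
#' Cluster labels become tips; branch lengths derive from merge heights.
#'
#' @param h an `hclust` (e.g. from [clusterMeanDendrogram()]).
#' @param path optional file; when NULL the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogramNewick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(path)) ape::write.tree(phy)
  else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
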