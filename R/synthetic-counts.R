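#' Configuration for the UMI count simulator
#'
#' Describes a realistic small single-cell dataset: `K` discrete cell
#' classes, each with a block of cluster-exclusive marker genes enriched by
#' a fold factor over a log-normal baseline; negative-binomial counts
#' (variance mu + mu^2/theta) with log-normal library sizes; optional
#' plate batch effects (per-gene log-fold perturbations per plate); and an
#' optional rank-1 within-cluster expression gradient in one cluster
#' (gene weights w*, standard-normal cell scores z*), emulating the
#' continuum observed inside a discrete type.
#'
#' @param n_clusters number of clusters K (default 7).
#' @param cells_per_cluster scalar or length-K vector (default 100).
#' @param n_genes total genes (default 500).
#' @param markers_per_cluster exclusive markers per cluster (default 28,
#'   so the default 7 clusters carry a ~196-gene marker panel, the size of
#'   the informative panel used for query-cell mapping).
#' @param marker_fold fold enrichment of markers (>= 1, default 4).
#' @param base_meanlog,base_sdlog log-normal baseline mean expression
#'   (defaults 1, 1, giving roughly 2,000 total molecules per cell over
#'   the default 500-gene panel).
#' @param theta NB dispersion (default 2).
#' @param libsize_sdlog log-normal SD of per-cell library-size factors
#'   (default 0.3).
#' @param n_plates plates assigned round-robin (default 2).
#' @param plate_effect_sd per-gene log-normal plate effect SD (default 0 =
#'   no batch effect; the first plate is the reference).
#' @param gradient NULL, or a list with `cluster` (index), `n_genes`,
#'   `w_sd` (weight scale, default 0.5).
#' @return a `CountSimConfig` list.
#' @export
countSimConfig <- function(n_clusters = 7, cells_per_cluster = 100,
                           n_genes = 500, markers_per_cluster = 28,
                           marker_fold = 4, base_meanlog = 1,
                           base_sdlog = 1, theta = 2, libsize_sdlog = 0.3,
                           n_plates = 2, plate_effect_sd = 0,
                           gradient = NULL) {
  if (n_clusters < 1 || n_genes < 1) stop("sizes must be positive")
  if (marker_fold < 1) stop("marker_fold must be >= 1")
  sizes <- rep_len(cells_per_cluster, n_clusters)
  if (any(sizes < 1)) stop("cells_per_cluster must be positive")
  if (n_clusters * markers_per_cluster > n_genes)
    stop("not enough genes for the marker blocks")
  structure(list(n_clusters = n_clusters, sizes = sizes,
                 n_genes = n_genes,
                 markers_per_cluster = markers_per_cluster,
                 marker_fold = marker_fold, base_meanlog = base_meanlog,
                 base_sdlog = base_sdlog, theta = theta,
                 libsize_sdlog = libsize_sdlog, n_plates = n_plates,
                 plate_effect_sd = plate_effect_sd, gradient = gradient),
            class = "CountSimConfig")
}

#' Simulate a UMI count matrix with known structure
#'
#' Draws counts `y_gi ~ NB(mu_gi, theta)` with
#' `mu_gi = lib_i * base_g * fold_g(cluster_i) * exp(plate_gp) *
#' exp(w*_g z*_i)` (the last factor only on gradient genes in the gradient
#' cluster). Marker blocks are disjoint across clusters. Fully
#' reproducible given the seed.
#'
#' @param cfg a [countSimConfig()].
#' @param seed integer seed (mandatory).
#' @return list: `matrix` (count container with `plate` metadata),
#'   `assignment` ([ClusterAssignment-class], labels `C1..CK`), `markers`
#'   (list per cluster), `gradient` (NULL or list with `cluster`, `genes`,
#'   `w`, `z`), `profiles` (genes x clusters expected relative expression,
#'   columns summing to 1), `config`.
#' @export
simulateCounts <- function(cfg, seed) {
  stopifnot(inherits(cfg, "CountSimConfig"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  G <- cfg$n_genes; K <- cfg$n_clusters
  n <- sum(cfg$sizes)
  genes <- sprintf("g%04d", seq_len(G))
  cells <- sprintf("cell%04d", seq_len(n))
  cl <- rep(paste0("C", seq_len(K)), cfg$sizes)
  base <- rlnorm(G, cfg$base_meanlog, cfg$base_sdlog)
  fold <- matrix(1, G, K)
  marker_idx <- matrix(sample.int(G, K * cfg$markers_per_cluster),
                       ncol = K)
  for (j in seq_len(K)) fold[marker_idx[, j], j] <- cfg$marker_fold
  markers <- lapply(seq_len(K), function(j) genes[marker_idx[, j]])
  names(markers) <- paste0("C", seq_len(K))
  plate <- paste0("P", 1 + (seq_len(n) - 1) %% cfg$n_plates)
  plate_eff <- matrix(0, G, cfg$n_plates)
  if (cfg$plate_effect_sd > 0 && cfg$n_plates > 1)
    plate_eff[, -1] <- rnorm(G * (cfg$n_plates - 1), 0,
                             cfg$plate_effect_sd)
  grad <- NULL
  gmat <- matrix(0, G, n)
  if (!is.null(cfg$gradient)) {
    gc <- cfg$gradient$cluster
    ng <- cfg$gradient$n_genes
    w_sd <- if (is.null(cfg$gradient$w_sd)) 0.5 else cfg$gradient$w_sd
    pool <- setdiff(seq_len(G), as.vector(marker_idx))
    gidx <- sample(pool, ng)
    w <- rnorm(ng, 0, w_sd)
    in_gc <- which(cl == paste0("C", gc))
    z <- rnorm(length(in_gc))
    gmat[gidx, in_gc] <- w %o% z
    grad <- list(cluster = paste0("C", gc), genes = genes[gidx], w = w,
                 z = setNames(z, cells[in_gc]))
  }
  lib <- rlnorm(n, 0, cfg$libsize_sdlog)
  kidx <- as.integer(sub("C", "", cl))
  pidx <- as.integer(sub("P", "", plate))
  mu <- (base * fold[, kidx]) * exp(plate_eff[, pidx] + gmat)
  mu <- sweep(mu, 2, lib, `*`)
  y <- matrix(rnbinom(G * n, mu = mu, size = cfg$theta), G, n)
  meta <- data.frame(plate = plate, dataset = "synthetic",
                     age_group = "sim", row.names = cells)
  profiles <- base * fold
  profiles <- sweep(profiles, 2, colSums(profiles), `/`)
  dimnames(profiles) <- list(genes, paste0("C", seq_len(K)))
  list(matrix = CountMatrix(y, genes, cells, meta),
       assignment = ClusterAssignment(setNames(cl, cells)),
       markers = markers, gradient = grad, profiles = profiles,
       config = cfg)
}

#' Simulate PatchSeq query cells from reference profiles
#'
#' Each query cell is sampled from its true cluster's expected expression
#' profile with NB noise at a given sequencing depth:
#' `y_g ~ NB(depth * p_g(cluster), dispersion)`.
#'
#' @param reference output of [simulateCounts()] (its `profiles` are
#'   used), or a genes x clusters profile matrix with columns summing
#'   to 1.
#' @param n_cells query cells to draw.
#' @param depth expected total molecules per cell (default 5000).
#' @param dispersion NB size parameter (default 2).
#' @param seed integer seed.
#' @param labels optional true labels (recycled); default: uniform over
#'   clusters.
#' @return list: `query` (count container), `labels` (named character
#'   ground truth).
#' @export
simulatePatchseqCells <- function(reference, n_cells, depth = 5000,
                                  dispersion = 2, seed = 1,
                                  labels = NULL) {
  profiles <- if (is.list(reference)) reference$profiles else reference
  set.seed(seed)
  K <- ncol(profiles)
  if (n_cells == 0) {
    m <- CountMatrix(matrix(0L, nrow(profiles), 0,
                            dimnames = list(rownames(profiles), NULL)),
                     rownames(profiles), character(0))
    return(list(query = m, labels = setNames(character(0), character(0))))
  }
  if (is.null(labels))
    labels <- colnames(profiles)[sample.int(K, n_cells, replace = TRUE)]
  labels <- rep_len(labels, n_cells)
  cells <- sprintf("ps%04d", seq_len(n_cells))
  y <- vapply(seq_len(n_cells), function(i) {
    mu <- depth * profiles[, labels[i]]
    rnbinom(nrow(profiles), mu = mu, size = dispersion)
  }, numeric(nrow(profiles)))
  list(query = CountMatrix(y, rownames(profiles), cells),
       labels = setNames(labels, cells))
}
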