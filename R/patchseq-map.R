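#' Variance filter on the query (PatchSeq) panel
#'
#' Retains marker-panel genes whose standard deviation across the query
#' dataset is at least `sd_min` (genes with SD strictly below the threshold
#' are excluded; the boundary SD = `sd_min` is kept). The SD is the
#' population SD of the configured expression scale — raw read counts by
#' default, matching the read-count scoring.
#'
#' @param query count container holding the query cells (>= 2 cells),
#'   restricted to (or containing) the marker panel.
#' @param panel character marker gene symbols; defaults to all query genes.
#' @param sd_min threshold (default 1).
#' @param log_scale compute the SD on log2(x+1) values instead of raw.
#' @return character vector of retained gene ids G.
#' @export
filterQueryGenes <- function(query, panel = rownames(query), sd_min = 1,
                             log_scale = FALSE) {
  validateCountMatrix(query, allow_real = TRUE)
  if (ncol(query) < 2) stop("need >= 2 query cells")
  panel <- intersect(as.character(panel), rownames(query))
  if (!length(panel)) stop("no panel genes present in the query")
  x <- counts(query, dense = TRUE)[panel, , drop = FALSE]
  if (log_scale) x <- log2(x + 1)
  mu <- rowMeans(x)
  popsd <- sqrt(rowMeans((x - mu)^2))
  keep <- panel[popsd >= sd_min]
  if (!length(keep))
    stop("variance filter removed every panel gene (all SD < ", sd_min, ")")
  keep
}

.nullGeneDraws <- function(n_universe, g, B, seed, exhaustive = FALSE) {
  if (exhaustive) {
    perm <- .allPermutations(n_universe)
    draws <- unique(perm[, seq_len(g), drop = FALSE])
    return(t(draws))
  }
  set.seed(seed)
  vapply(seq_len(B), function(b) sample.int(n_universe, g),
         integer(g))
}

.bootstrapPvals <- function(X, sp, G, B, seed, exhaustive = FALSE) {
  # X: cells x |G| observed counts (columns in G order);
  # sp: SpecificityMatrix. Returns list(obs, pvals).
  miss <- setdiff(G, rownames(sp@specificity))
  if (length(miss))
    stop("gene(s) missing from the specificity matrix: ",
         paste(miss, collapse = ", "))
  uni <- sp@universe
  bad <- setdiff(G, uni)
  if (length(bad))
    stop("gene(s) outside the specificity universe: ",
         paste(bad, collapse = ", "))
  if (length(uni) < 2 * length(G))
    stop("background universe (", length(uni),
         ") smaller than 2 x |G| = ", 2 * length(G))
  S <- sp@specificity[uni, , drop = FALSE]
  obs <- X %*% S[G, , drop = FALSE]
  draws <- .nullGeneDraws(length(uni), length(G), B, seed, exhaustive)
  nB <- ncol(draws)
  ge <- matrix(0, nrow(X), ncol(S))
  for (b in seq_len(nB)) {
    sb <- X %*% S[draws[, b], , drop = FALSE]
    ge <- ge + (sb >= obs - 1e-12)
  }
  pv <- if (exhaustive) ge / nB else (1 + ge) / (nB + 1)
  dimnames(obs) <- dimnames(pv) <- list(rownames(X), colnames(S))
  list(obs = obs, pvals = pv, B = nB)
}

#' Map one PatchSeq cell to reference cell types
#'
#' Observed score per cluster: the cell's read count of every retained
#' marker gene multiplied by that gene's specificity, summed over genes.
#' The null repeats the sum `B` times on random gene lists of equal size
#' drawn without replacement from the background universe, pairing the
#' i-th drawn gene's specificity with the i-th observed count (counts keep
#' their order; gene identity is randomized). Empirical p per cluster uses
#' the add-one convention `p = (1 + #(null >= observed)) / (B + 1)`, so p
#' lies in \[1/(B+1), 1\]. The cell is assigned to the cluster with minimal
#' p when that p is below `alpha`; otherwise (or on a tie for the minimum)
#' it is "undefined".
#'
#' @param x named numeric: the query cell's counts on the retained genes G.
#' @param sp a [SpecificityMatrix-class] from the reference.
#' @param B bootstrap repetitions (default 10000).
#' @param alpha assignment threshold on the minimal p (default 0.05).
#' @param seed integer RNG seed.
#' @param exhaustive enumerate every ordered gene draw instead of sampling
#'   (tiny universes only); p is then the exact null tail probability.
#' @return list with `scores`, `pvals` (named per cluster), `assigned`,
#'   `min_p`, `tie`.
#' @export
mapCell <- function(x, sp, B = 10000, alpha = 0.05, seed = 1,
                    exhaustive = FALSE) {
  stopifnot(is(sp, "SpecificityMatrix"))
  if (is.null(names(x))) stop("x must be named by gene")
  X <- matrix(as.numeric(x), 1, dimnames = list("cell", names(x)))
  bt <- .bootstrapPvals(X, sp, names(x), B, seed, exhaustive)
  pv <- bt$pvals[1, ]
  j <- which(pv == min(pv))
  tie <- length(j) > 1
  assigned <- if (!tie && min(pv) < alpha) names(pv)[j] else "undefined"
  list(scores = bt$obs[1, ], pvals = pv, assigned = assigned,
       min_p = min(pv), tie = tie)
}

#' Map a PatchSeq dataset to reference cell types
#'
#' Full specificity-weighted bootstrap assignment: computes the reference
#' gene-by-cluster specificity ([specificity()]), applies the query-side
#' variance filter to the marker panel ([filterQueryGenes()]), scores every
#' query cell against every cluster, and assigns each cell by bootstrap
#' p-value as in [mapCell()] (one shared set of `B` null gene lists is
#' drawn for all cells). Query cells should already have passed
#' [qcPatchseq()].
#'
#' @param query count container of PatchSeq cells.
#' @param reference reference count container.
#' @param ref_assignment [ClusterAssignment-class] for the reference cells.
#' @param panel marker gene symbols (e.g. a top-markers union); default
#'   all shared genes.
#' @param sd_min query variance filter threshold (default 1).
#' @param B,alpha,seed,exhaustive as in [mapCell()].
#' @param log_scale_sd compute the variance filter on log scale.
#' @param normalize_reference total-count-normalize the reference before
#'   computing specificity (default TRUE), so cluster means are not tilted
#'   by library-size differences; the query-side variance filter and the
#'   scores always use raw query read counts.
#' @return a [PatchSeqMapping-class].
#' @export
mapDataset <- function(query, reference, ref_assignment, panel = NULL,
                       sd_min = 1, B = 10000, alpha = 0.05, seed = 1,
                       exhaustive = FALSE, log_scale_sd = FALSE,
                       normalize_reference = TRUE) {
  validateCountMatrix(query, allow_real = TRUE)
  if (normalize_reference)
    reference <- normalizeTotal(reference, round_to_integer = FALSE)
  sp <- specificity(reference, ref_assignment)
  if (is.null(panel)) panel <- intersect(rownames(reference),
                                         rownames(query))
  if (ncol(query) == 0) {
    return(new("PatchSeqMapping",
               results = data.frame(cell_id = character(0),
                                    assigned = character(0),
                                    min_p = numeric(0), tie = logical(0)),
               scores = matrix(0, 0, ncol(sp@specificity)),
               pvals = matrix(0, 0, ncol(sp@specificity)),
               genesUsed = character(0), B = as.integer(B),
               alpha = alpha, seed = as.integer(seed)))
  }
  G <- filterQueryGenes(query, panel, sd_min = sd_min,
                        log_scale = log_scale_sd)
  X <- t(counts(query, dense = TRUE)[G, , drop = FALSE])
  bt <- .bootstrapPvals(X, sp, G, B, seed, exhaustive)
  pv <- bt$pvals
  res <- data.frame(cell_id = rownames(pv),
                    assigned = NA_character_,
                    min_p = NA_real_, tie = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pv))) {
    p <- pv[i, ]
    j <- which(p == min(p))
    res$tie[i] <- length(j) > 1
    res$min_p[i] <- min(p)
    res$assigned[i] <- if (!res$tie[i] && min(p) < alpha)
      colnames(pv)[j] else "undefined"
  }
  new("PatchSeqMapping", results = res, scores = bt$obs, pvals = pv,
      genesUsed = G, B = as.integer(bt$B), alpha = alpha,
      seed = as.integer(seed))
}
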