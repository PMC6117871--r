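.clusterMeans <- function(m, a) {
  cells <- checkAssignment(a, m, require_all = TRUE)
  lab <- clusterLabels(a)[cells]
  labs <- sort(unique(lab))
  sz <- vapply(labs, function(j) sum(lab == j), integer(1))
  if (any(sz == 0)) stop("empty cluster: ", paste(labs[sz == 0],
                                                  collapse = ", "))
  x <- counts(m)[, cells, drop = FALSE]
  means <- matrix(vapply(labs, function(j)
    as.numeric(Matrix::rowMeans(x[, lab == j, drop = FALSE])),
    numeric(nrow(x))), nrow(x), length(labs))
  posfrac <- matrix(vapply(labs, function(j)
    as.numeric(Matrix::rowMeans(x[, lab == j, drop = FALSE] > 0)),
    numeric(nrow(x))), nrow(x), length(labs))
  dimnames(means) <- dimnames(posfrac) <- list(rownames(m), labs)
  list(x = x, means = means, posfrac = posfrac,
       global = as.numeric(Matrix::rowMeans(x)))
}

#' Marker-gene enrichment scores
#'
#' For every gene i and cluster j computes the molecule enrichment
#' `enrich[i,j]` = (mean of E over cells of j) / (mean of E over all N
#' cells), the fraction of positive cells `posfrac[i,j]` = fraction of
#' cells of j with E > 0, and the ranking score
#' `S[i,j] = enrich[i,j] * posfrac[i,j]^power` for every requested power.
#' The power sets the weight given to the fraction of positive cells;
#' power 0 ranks purely by enrichment. Genes with global mean 0 carry
#' enrich = 0 by convention. Scores are typically computed on
#' total-count-normalized counts ([normalizeTotal()]); raw counts work too.
#'
#' @param m count container.
#' @param a a [ClusterAssignment-class]; clusters must be non-empty.
#' @param powers numeric vector of powers (default `c(0, 0.5, 1)`).
#' @return a [MarkerScores-class].
#' @export
enrichmentScores <- function(m, a, powers = c(0, 0.5, 1)) {
  validateCountMatrix(m, allow_real = TRUE)
  cm <- .clusterMeans(m, a)
  enrich <- cm$means / ifelse(cm$global > 0, cm$global, Inf)  # 0 when global 0
  scores <- lapply(powers, function(p) {
    s <- enrich * cm$posfrac^p  # 0^0 == 1 in R: S at power 0 equals enrich
    dimnames(s) <- dimnames(enrich)
    s
  })
  names(scores) <- paste0("power_", powers)
  new("MarkerScores", enrich = enrich, posfrac = cm$posfrac,
      scores = scores, powers = as.numeric(powers))
}

#' Top marker genes per cluster
#'
#' For every cluster and every power, ranks genes by the combined score S
#' (descending; ties broken lexicographically by gene id) and keeps the top
#' `x`. The union list per cluster tags every gene with the powers that
#' contributed it.
#'
#' @param scores a [MarkerScores-class].
#' @param x how many genes per cluster and power.
#' @return list with `per_power` (nested list power -> cluster ->
#'   character vector) and `union` (cluster -> data.frame gene/powers).
#' @export
topMarkers <- function(scores, x) {
  stopifnot(is(scores, "MarkerScores"))
  if (x > nrow(scores@enrich))
    stop("x exceeds the number of genes")
  clusters <- colnames(scores@enrich)
  per_power <- lapply(scores@scores, function(s) {
    out <- lapply(clusters, function(j) {
      ord <- order(-s[, j], rownames(s))
      rownames(s)[ord[seq_len(x)]]
    })
    names(out) <- clusters
    out
  })
  union <- lapply(clusters, function(j) {
    hits <- lapply(names(per_power), function(pw) per_power[[pw]][[j]])
    genes <- sort(unique(unlist(hits)))
    pws <- vapply(genes, function(g)
      paste(scores@powers[vapply(hits, function(h) g %in% h, logical(1))],
            collapse = ","), character(1))
    data.frame(gene = genes, powers = unname(pws), stringsAsFactors = FALSE)
  })
  names(union) <- clusters
  list(per_power = per_power, union = union)
}

#' Gene-by-cluster specificity
#'
#' `specificity[g, j]` = (mean expression of g in cluster j) / (sum of g's
#' cluster means over all clusters): the expression-weighted cell-type
#' specificity convention, in which each expressed gene distributes one
#' unit of specificity across the cell types. Genes with all cluster means
#' zero get zeros and are flagged out of the background universe used by
#' PatchSeq mapping.
#'
#' @param m reference count container.
#' @param a a [ClusterAssignment-class]; clusters must be non-empty.
#' @return a [SpecificityMatrix-class].
#' @export
specificity <- function(m, a) {
  validateCountMatrix(m, allow_real = TRUE)
  cm <- .clusterMeans(m, a)
  tot <- rowSums(cm$means)
  sp <- cm$means / ifelse(tot > 0, tot, Inf)
  dimnames(sp) <- dimnames(cm$means)
  new("SpecificityMatrix", specificity = sp,
      universe = rownames(sp)[tot > 0])
}
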