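# small builders shared across test files

toyMatrix <- function(x, genes = sprintf("g%d", seq_len(nrow(x))),
                      cells = sprintf("c%d", seq_len(ncol(x))),
                      meta = NULL) {
  CountMatrix(x, genes, cells, meta)
}

# literal transcription of the marker-score formulas, coded independently
# of the package implementation: plain double loops over genes and clusters
oracleMarkerScores <- function(E, labels, powers) {
  genes <- rownames(E); clusters <- sort(unique(labels))
  enrich <- posfrac <- matrix(0, nrow(E), length(clusters),
                              dimnames = list(genes, clusters))
  for (i in seq_len(nrow(E))) {
    global <- mean(E[i, ])
    for (jj in seq_along(clusters)) {
      k_in_j <- which(labels == clusters[jj])
      m_j <- sum(E[i, k_in_j]) / length(k_in_j)
      enrich[i, jj] <- if (global > 0) m_j / global else 0
      posfrac[i, jj] <- sum(E[i, k_in_j] > 0) / length(k_in_j)
    }
  }
  scores <- lapply(powers, function(p) enrich * posfrac^p)
  list(enrich = enrich, posfrac = posfrac, scores = scores)
}

# brute-force BH step-up from its definition: q_(i) = min_{j >= i} m p_(j)/j
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- qs
  out
}

adjustedRand <- function(a, b) {
  # mclust provides the reference implementation in Suggests
  mclust::adjustedRandIndex(a, b)
}
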