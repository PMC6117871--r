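#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min over the sorted tail of m*p_(j)/j,
#' capped at 1. Thin validated wrapper over `p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return numeric vector of q-values, same order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04, 0.5))
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney/rank-sum test of two independent samples. For
#' `length(a) + length(b) <= max_exact` the p-value is computed by
#' exhaustive enumeration of all group assignments of the pooled (average)
#' ranks, which remains exact under ties; otherwise the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param a,b numeric samples.
#' @param max_exact pooled-size ceiling for exact enumeration (default 10).
#' @return list with `statistic` (rank sum of `a`), `p`, `method`.
#' @export
ranksumTest <- function(a, b, max_exact = 10) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b); N <- na + nb
  if (na < 1 || nb < 1) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  if (N <= max_exact) {
    idx <- combn(N, na)
    sums <- colSums(matrix(r[idx], nrow = na))
    p <- min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
    return(list(statistic = W, p = p, method = "exact"))
  }
  E <- na * (N + 1) / 2
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / (N * (N - 1))
  V <- na * nb / 12 * ((N + 1) - tiecor)
  if (V <= 0) return(list(statistic = W, p = 1, method = "normal"))
  z <- (W - E - sign(W - E) * 0.5) / sqrt(V)
  list(statistic = W, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene: two-sided rank-sum p-value at the single-cell level
#' ([ranksumTest()]), BH adjustment across all genes detected in at least
#' one cell of either group, and the fold change
#' `(mean_A + eps) / (mean_B + eps)`. A gene is called significant when
#' `q < q_thresh` and `|log2 FC| >= log2(fc_thresh)` (fold change above
#' the threshold in either direction). Run on normalized counts for
#' interpretable fold changes.
#'
#' @param m count container.
#' @param groupA,groupB disjoint cell id vectors, each >= 3 cells.
#' @param q_thresh FDR threshold (default 0.05).
#' @param fc_thresh fold-change threshold (default 2).
#' @param eps pseudocount added to both means (default 0.01 normalized
#'   molecules).
#' @return data.frame per gene: `gene`, `mean_a`, `mean_b`, `log2fc`, `p`,
#'   `q`, `neglog10_p`, `tested`, `significant` — a volcano-ready table.
#' @export
wilcoxonDE <- function(m, groupA, groupB, q_thresh = 0.05, fc_thresh = 2,
                       eps = 0.01) {
  validateCountMatrix(m, allow_real = TRUE)
  groupA <- as.character(groupA); groupB <- as.character(groupB)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ",
         paste(head(intersect(groupA, groupB), 5), collapse = ", "))
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("both groups need >= 3 cells")
  xa <- counts(subsetCounts(m, cells = groupA), dense = TRUE)
  xb <- counts(subsetCounts(m, cells = groupB), dense = TRUE)
  tested <- rowSums(xa > 0) + rowSums(xb > 0) >= 1
  p <- rep(NA_real_, nrow(m))
  for (g in which(tested))
    p[g] <- ranksumTest(xa[g, ], xb[g, ])$p
  q <- bhAdjust(p)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  l2fc <- log2((ma + eps) / (mb + eps))
  sig <- tested & !is.na(q) & q < q_thresh & abs(l2fc) >= log2(fc_thresh)
  data.frame(gene = rownames(m), mean_a = ma, mean_b = mb, log2fc = l2fc,
             p = p, q = q, neglog10_p = -log10(p), tested = tested,
             significant = sig, row.names = NULL, stringsAsFactors = FALSE)
}

.spearmanP <- function(rho, n, rt, rg_list = NULL, perms = NULL) {
  t <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Spearman correlation screen against a target gene
#'
#' Within a set of cells (typically one cluster), computes Spearman's rho
#' between every gene and a target gene (e.g. Pvalb), with average-rank tie
#' handling. P-values come from the t approximation, or from exhaustive
#' permutation of the target's ranks when `n <= 9`. BH adjustment runs over
#' all testable genes except the target itself, which is reported with
#' class "target" and excluded from classification. Genes are classified
#' positive when `rho > rho_thresh` and `q < q_thresh`, negative when
#' `rho < -rho_thresh` and `q < q_thresh`, else "ns".
#'
#' @param m count container.
#' @param cells cell ids to screen over (>= 5).
#' @param target_gene gene symbol; must vary across the cells.
#' @param rho_thresh correlation threshold (default 0.15).
#' @param q_thresh FDR threshold (default 0.05).
#' @return data.frame per gene: `gene`, `rho`, `p`, `q`, `class`.
#' @export
spearmanScreen <- function(m, cells, target_gene, rho_thresh = 0.15,
                           q_thresh = 0.05) {
  validateCountMatrix(m, allow_real = TRUE)
  x <- counts(subsetCounts(m, cells = as.character(cells)), dense = TRUE)
  n <- ncol(x)
  if (n < 5) stop("need >= 5 cells")
  if (!target_gene %in% rownames(x))
    stop("target gene ", target_gene, " not in matrix")
  tgt <- x[target_gene, ]
  if (var(tgt) == 0) stop("zero-variance target gene")
  rt <- rank(tgt)
  R <- t(apply(x, 1, rank))
  vr <- apply(R, 1, var)
  rho <- rep(NA_real_, nrow(x))
  rho[vr > 0] <- suppressWarnings(
    as.numeric(cor(t(R[vr > 0, , drop = FALSE]), rt)))
  p <- rep(NA_real_, nrow(x))
  if (n <= 9) {
    perm <- .allPermutations(n)
    Mt <- matrix(rt[perm], nrow = nrow(perm))
    den <- (n - 1) * sd(rt)
    for (g in which(vr > 0)) {
      sg <- sd(R[g, ])
      rho_b <- (Mt %*% R[g, ] - n * mean(rt) * mean(R[g, ])) / (den * sg)
      p[g] <- mean(abs(rho_b) >= abs(rho[g]) - 1e-12)
    }
  } else {
    p[vr > 0] <- .spearmanP(rho[vr > 0], n)
  }
  isTarget <- rownames(x) == target_gene
  q <- rep(NA_real_, nrow(x))
  fam <- !isTarget & !is.na(p)
  q[fam] <- bhAdjust(p[fam])
  cls <- rep("ns", nrow(x))
  cls[fam & rho > rho_thresh & q < q_thresh] <- "positive"
  cls[fam & rho < -rho_thresh & q < q_thresh] <- "negative"
  cls[isTarget] <- "target"
  data.frame(gene = rownames(x), rho = rho, p = p, q = q, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
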